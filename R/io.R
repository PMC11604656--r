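#' Read a 10x-style spot expression directory
#'
#' Expects `matrix.mtx[.gz]`, `barcodes.tsv[.gz]`, `features.tsv[.gz]` and a
#' tissue positions CSV (`tissue_positions_list.csv` without header, or a
#' headered `tissue_positions.csv` variant, auto-detected by sniffing the
#' first line). The MatrixMarket file stores genes in rows and barcodes in
#' columns (10x convention); it is transposed to the package's spot x gene
#' orientation, and its 1-based coordinates are handled by the reader. The
#' returned matrix is restricted to `in_tissue == 1` spots; out-of-tissue
#' barcodes remain in `positions`.
#'
#' @param dir_path Directory with the files above.
#' @param pixel_to_um Scale factor from position pixels to micrometres
#'   (default 1: positions already in um, as written by
#'   [write_spot_dataset()]).
#' @return A [spot_dataset()].
#' @export
read_spot_dataset <- function(dir_path, pixel_to_um = 1) {
  mtx <- find_one(dir_path, c("matrix.mtx", "matrix.mtx.gz"))
  bc <- find_one(dir_path, c("barcodes.tsv", "barcodes.tsv.gz"))
  ft <- find_one(dir_path, c("features.tsv", "features.tsv.gz"))
  pos_file <- find_one(dir_path, c("tissue_positions_list.csv",
                                   "tissue_positions.csv",
                                   "tissue_positions_list.csv.gz",
                                   "tissue_positions.csv.gz"))
  first <- readLines(mtx, n = 1)
  if (!grepl("^%%MatrixMarket +matrix +coordinate +(integer|real) +general",
             first)) {
    abort(paste0("malformed MatrixMarket header: ", first))
  }
  m <- Matrix::readMM(mtx)
  barcodes <- readr::read_tsv(bc, col_names = FALSE,
                              show_col_types = FALSE)[[1]]
  features <- readr::read_tsv(ft, col_names = FALSE,
                              show_col_types = FALSE)[[1]]
  if (length(barcodes) != ncol(m)) {
    abort("barcodes length does not match matrix columns")
  }
  if (length(features) != nrow(m)) {
    abort("features length does not match matrix rows")
  }
  if (anyDuplicated(barcodes)) abort("duplicate barcodes")
  counts <- Matrix::t(m)
  dimnames(counts) <- list(barcodes, features)

  positions <- read_tissue_positions(pos_file, pixel_to_um)
  if (!all(barcodes %in% positions$barcode)) {
    abort("positions file does not cover all barcodes")
  }
  keep <- positions$barcode[positions$in_tissue == 1]
  counts <- counts[rownames(counts) %in% keep, , drop = FALSE]
  spot_dataset(counts, positions)
}

read_tissue_positions <- function(path, pixel_to_um = 1) {
  first <- readLines(path, n = 1)
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  headered <- grepl("^barcode", first)
  pos <- readr::read_csv(path, col_names = headered,
                         show_col_types = FALSE)
  if (!headered) names(pos) <- cols
  missing <- setdiff(cols, names(pos))
  if (length(missing) > 0) {
    abort(paste0("positions file missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!is.numeric(pos$pxl_row_in_fullres) ||
      !is.numeric(pos$pxl_col_in_fullres)) {
    abort("non-numeric position coordinates")
  }
  pos |>
    dplyr::mutate(x_um = .data$pxl_col_in_fullres * pixel_to_um,
                  y_um = .data$pxl_row_in_fullres * pixel_to_um)
}

#' Write a spot dataset as a 10x-style directory
#'
#' Writes `matrix.mtx` (coordinate integer general, genes x barcodes),
#' `features.tsv`, `barcodes.tsv` and a header-less
#' `tissue_positions_list.csv` with columns
#' `barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres`
#' (pixel coordinates taken as micrometres, scale 1).
#'
#' @param ds A [spot_dataset()] (raw counts are written).
#' @param dir_path Output directory (created if needed).
#' @param gzip Write gzip-compressed matrix/barcodes/features.
#' @return Invisibly, the vector of written file paths.
#' @export
write_spot_dataset <- function(ds, dir_path, gzip = FALSE) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (n_genes(ds) == 0) abort("refusing to write a dataset with no genes")
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".gz" else ""
  mtx_path <- file.path(dir_path, paste0("matrix.mtx", ext))
  write_mtx_integer(Matrix::t(ds$counts), mtx_path, gzip)
  bc_path <- file.path(dir_path, paste0("barcodes.tsv", ext))
  ft_path <- file.path(dir_path, paste0("features.tsv", ext))
  readr::write_tsv(tibble(x = rownames(ds$counts)), bc_path,
                   col_names = FALSE)
  readr::write_tsv(tibble(x = colnames(ds$counts)), ft_path,
                   col_names = FALSE)
  pos_path <- file.path(dir_path, "tissue_positions_list.csv")
  pos <- ds$positions |>
    dplyr::transmute(.data$barcode, .data$in_tissue, .data$array_row,
                     .data$array_col,
                     pxl_row_in_fullres = .data$y_um,
                     pxl_col_in_fullres = .data$x_um)
  readr::write_csv(pos, pos_path, col_names = FALSE)
  invisible(c(mtx_path, bc_path, ft_path, pos_path))
}

# Matrix::writeMM types all matrices "real"; the 10x dialect wants
# "coordinate integer general", so integers are written directly.
write_mtx_integer <- function(m, path, gzip = FALSE) {
  m <- methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix")
  if (any(m@x != round(m@x))) abort("non-integer counts")
  con <- if (gzip) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(m@x))), con)
  if (length(m@x) > 0) {
    writeLines(paste(m@i + 1L, m@j + 1L, format(m@x, scientific = FALSE,
                                                trim = TRUE)), con)
  }
  invisible(path)
}

find_one <- function(dir_path, candidates) {
  hits <- file.path(dir_path, candidates)
  hits <- hits[file.exists(hits)]
  if (length(hits) == 0) {
    abort(paste0("none of ", paste(candidates, collapse = "/"),
                 " found in ", dir_path))
  }
  hits[1]
}

read_schema_table <- function(path, required, reader, what) {
  tbl <- reader(path)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl
}

#' Read a gene annotation table
#'
#' TSV with required columns `gene_id`, `chromosome`, `start`, `end`
#' (0-based half-open base pairs); extra columns are preserved.
#'
#' @param tsv_path Path to the TSV.
#' @return Tibble of gene annotations.
#' @export
read_gene_annotation <- function(tsv_path) {
  tbl <- read_schema_table(tsv_path, c("gene_id", "chromosome", "start",
                                       "end"),
                           function(p) readr::read_tsv(p,
                                                       show_col_types = FALSE),
                           "gene annotation")
  if (anyDuplicated(tbl$gene_id)) abort("duplicate gene_id in annotation")
  if (!is.numeric(tbl$start) || !is.numeric(tbl$end)) {
    abort("non-numeric gene coordinates")
  }
  if (any(tbl$start >= tbl$end)) abort("annotation interval with start >= end")
  tbl
}

#' Read per-clone copy-number profiles
#'
#' TSV with required columns `clone`, `chromosome`, `start`, `end`,
#' `copy_number` (intervals 0-based half-open, non-overlapping within a
#' clone).
#'
#' @param tsv_path Path to the TSV.
#' @param ploidy Baseline ploidy assumed outside listed intervals.
#' @return Tibble of CNV intervals with a `ploidy` attribute.
#' @export
read_cnv_profiles <- function(tsv_path, ploidy = 2) {
  tbl <- read_schema_table(tsv_path, c("clone", "chromosome", "start", "end",
                                       "copy_number"),
                           function(p) readr::read_tsv(p,
                                                       show_col_types = FALSE),
                           "CNV profile")
  if (any(tbl$copy_number < 0)) abort("negative copy number")
  if (any(tbl$start >= tbl$end)) abort("CNV interval with start >= end")
  overlaps <- tbl |>
    dplyr::group_by(.data$clone, .data$chromosome) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(bad = any(.data$start < dplyr::lag(.data$end),
                               na.rm = TRUE), .groups = "drop")
  if (any(overlaps$bad)) abort("overlapping CNV intervals within a clone")
  attr(tbl, "ploidy") <- ploidy
  tbl
}

#' Read a nucleus table
#'
#' CSV with required columns `nucleus_id`, `x_um`, `y_um`, `area_um2`;
#' extra columns (e.g. `true_clone`) are preserved.
#'
#' @param csv_path Path to the CSV.
#' @return Tibble of nuclei.
#' @export
read_nuclei <- function(csv_path) {
  tbl <- read_schema_table(csv_path, c("nucleus_id", "x_um", "y_um",
                                       "area_um2"),
                           function(p) readr::read_csv(p,
                                                       show_col_types = FALSE),
                           "nucleus table")
  if (!is.numeric(tbl$x_um) || !is.numeric(tbl$y_um)) {
    abort("non-numeric nucleus coordinates")
  }
  if (any(tbl$area_um2 <= 0)) abort("nucleus area must be > 0")
  tbl
}

#' Read a structure table for microtube quantification
#'
#' CSV with required columns `sample_id`, `crop_id`, `class`
#' (`cell`/`microtube`), `area_um2`.
#'
#' @param csv_path Path to the CSV.
#' @return Tibble of structures.
#' @export
read_structures <- function(csv_path) {
  tbl <- read_schema_table(csv_path, c("sample_id", "crop_id", "class",
                                       "area_um2"),
                           function(p) readr::read_csv(p,
                                                       show_col_types = FALSE),
                           "structure table")
  bad <- setdiff(unique(tbl$class), c("cell", "microtube"))
  if (length(bad) > 0) {
    abort(paste0("unknown structure class: ", paste(bad, collapse = ", ")))
  }
  if (any(tbl$area_um2 <= 0)) abort("structure area must be > 0")
  tbl
}

#' Default pipeline configuration
#'
#' All thresholds of the analysis with their defaults: cluster-size floor
#' for the heterogeneity index (5 spots), gene-detection QC (10% of spots in
#' human mode, 10 spots in PDX mode), microtube area filters (cells kept at
#' >= 10 um^2, microtubes kept at > 2 um^2), two clones, and the synthetic
#' generator's study conditions.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    # QC
    min_counts_per_spot = 100,
    min_genes_per_spot = 50,
    gene_filter_mode = "fraction",  # "fraction" (human) or "spots" (PDX)
    gene_min_fraction = 0.10,
    gene_min_spots = 10,
    # segmentation / clone mapping
    k_clones = 2,
    beta = NULL,                    # NULL: data-driven default
    max_iter = 100,
    n_starts = 5,
    knn = 15,
    n_pcs = 20,
    # heterogeneity
    het_k_max = 12,
    min_cluster_spots = 5,
    # geometry
    alpha = NULL,                   # NULL: 1 / (1.5 * spot spacing)
    # microtubes
    cell_min_area_um2 = 10,
    microtube_min_area_um2 = 2,
    crop_aggregate = "mean",
    # synthetic study conditions
    sim = list(n_rows = 40, n_cols = 40, spacing_um = 100, n_genes = 2000,
               n_informative = 200, cn_gain = 4, cn_base = 2,
               contamination = 0.2, baseline_mean = 0.5,
               gene_logmean_sd = 1, nb_dispersion = 2, libsize_sd = 0.3,
               layout = "half_split", blob_smooth_um = 300,
               nuclei_density_per_mm2 = 1000,
               fish_efficiency = 0.9, fish_false_rate = 0.05)
  )
}

#' Read and validate a YAML configuration file
#'
#' Unknown keys produce a warning (not an error) and are kept; known keys
#' override the defaults from [default_config()].
#'
#' @param path Path to a YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    warn(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, user)
  if (!is.null(cfg$gene_filter_mode) &&
      !cfg$gene_filter_mode %in% c("fraction", "spots")) {
    abort("gene_filter_mode must be 'fraction' or 'spots'")
  }
  cfg
}

#' Write a complete synthetic sample to disk
#'
#' Materialises one synthetic sample in the exact on-disk dialects the
#' readers consume: the 10x-style count directory, `gene_annotation.tsv`,
#' `cnv_profiles.tsv`, `nuclei.csv`, `fish_counts.csv` and `truth.json`
#' (ground-truth clone labels and parameters).
#'
#' @param truth A [make_synthetic_truth()] object.
#' @param dir_path Output directory.
#' @param density_per_mm2 Nucleus density for [simulate_nuclei()].
#' @param probe_cn_per_clone Probe copy numbers for
#'   [simulate_fish_counts()]; default two probes at the truth's gain/base
#'   copy numbers.
#' @param efficiency,false_rate FISH simulation parameters.
#' @return Invisibly, `dir_path`.
#' @export
write_synthetic_sample <- function(truth, dir_path,
                                   density_per_mm2 = 1000,
                                   probe_cn_per_clone = NULL,
                                   efficiency = 0.9, false_rate = 0.05) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_counts(truth)
  write_spot_dataset(ds, dir_path)
  readr::write_tsv(truth$annotation, file.path(dir_path,
                                               "gene_annotation.tsv"))
  readr::write_tsv(truth$cnv_profiles, file.path(dir_path,
                                                 "cnv_profiles.tsv"))
  nuc <- simulate_nuclei(truth$clone_field, density_per_mm2,
                         seed = truth$params$seed + 3L)
  readr::write_csv(nuc, file.path(dir_path, "nuclei.csv"))
  if (is.null(probe_cn_per_clone)) {
    cn_a <- truth$gene_dosage["A", truth$informative_genes[1]] * 2
    cn_b <- truth$gene_dosage["B", truth$informative_genes[1]] * 2
    probe_cn_per_clone <- list(cen8 = c(A = cn_a, B = cn_b),
                               MDM2 = c(A = cn_a, B = cn_b))
  }
  fish <- simulate_fish_counts(nuc, probe_cn_per_clone, efficiency,
                               false_rate, seed = truth$params$seed + 4L)
  readr::write_csv(fish, file.path(dir_path, "fish_counts.csv"))
  truth_json <- list(
    params = unclass(truth$params),
    clone = setNames(as.list(truth$clone_field$clone),
                     truth$clone_field$spot_id),
    informative_genes = truth$informative_genes
  )
  jsonlite::write_json(truth_json, file.path(dir_path, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir_path)
}

#' Read the ground truth written by [write_synthetic_sample()]
#' @param dir_path Sample directory.
#' @return List with `params`, `clone` (named vector), `informative_genes`.
#' @export
read_truth <- function(dir_path) {
  tr <- jsonlite::read_json(file.path(dir_path, "truth.json"),
                            simplifyVector = TRUE)
  tr$clone <- unlist(tr$clone)
  tr
}
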