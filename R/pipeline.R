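#' Simulate a synthetic sample to disk
#'
#' Builds the generator parameters from `config$sim`, creates the
#' two-clone ground truth and writes the complete sample
#' ([write_synthetic_sample()]).
#'
#' @param dir_path Output directory.
#' @param config Configuration list ([default_config()]).
#' @param seed Seed overriding `config$seed`.
#' @return Invisibly, `dir_path`.
#' @export
run_simulate <- function(dir_path, config = default_config(),
                         seed = config$seed) {
  s <- config$sim
  params <- sim_params(
    n_rows = s$n_rows, n_cols = s$n_cols, spacing_um = s$spacing_um,
    n_genes = s$n_genes, baseline_mean = s$baseline_mean,
    gene_logmean_sd = s$gene_logmean_sd, nb_dispersion = s$nb_dispersion,
    libsize_sd = s$libsize_sd, contamination = s$contamination,
    layout = s$layout, blob_smooth_um = s$blob_smooth_um, seed = seed
  )
  truth <- make_synthetic_truth(params, n_informative = s$n_informative,
                                cn_gain = s$cn_gain, cn_base = s$cn_base)
  write_synthetic_sample(truth, dir_path,
                         density_per_mm2 = s$nuclei_density_per_mm2,
                         efficiency = s$fish_efficiency,
                         false_rate = s$fish_false_rate)
  invisible(dir_path)
}

preprocess_dataset <- function(ds, config) {
  ds <- filter_spots(ds, min_counts = config$min_counts_per_spot,
                     min_genes = config$min_genes_per_spot)
  ds <- if (config$gene_filter_mode == "fraction") {
    filter_genes(ds, min_fraction = config$gene_min_fraction)
  } else {
    filter_genes(ds, min_spots = config$gene_min_spots)
  }
  normalize_log1p(ds)
}

#' Run clone mapping on a sample directory
#'
#' Reads the sample, applies QC and normalization, maps clones, and (when a
#' `truth.json` is present) scores the assignment against the ground truth.
#'
#' @param sample_dir Directory written by [run_simulate()] (or any 10x-style
#'   directory with `gene_annotation.tsv` and `cnv_profiles.tsv`).
#' @param config Configuration list.
#' @param seed Seed overriding `config$seed`.
#' @return List with `clone_map`, `dataset`, `graph`, `qc_state`,
#'   `accuracy` (tibble or NULL).
#' @export
run_clone_mapping <- function(sample_dir, config = default_config(),
                              seed = config$seed) {
  ds <- read_spot_dataset(sample_dir)
  ann <- read_gene_annotation(file.path(sample_dir, "gene_annotation.tsv"))
  profiles <- read_cnv_profiles(file.path(sample_dir, "cnv_profiles.tsv"))
  ds <- preprocess_dataset(ds, config)
  graph <- build_spot_graph(ds)
  cm <- map_clones(ds, ann, profiles, graph, beta = config$beta,
                   max_iter = config$max_iter, seed = seed,
                   n_starts = config$n_starts, knn = config$knn,
                   n_pcs = config$n_pcs)
  acc <- NULL
  if (file.exists(file.path(sample_dir, "truth.json"))) {
    truth <- read_truth(sample_dir)
    acc <- clone_accuracy(cm, truth$clone)
  }
  list(clone_map = cm, dataset = ds, graph = graph,
       qc_state = ds$qc_state, accuracy = acc)
}

#' Heterogeneity index of one preprocessed dataset
#'
#' Counts the transcriptionally distinct tissue regions of a sample and
#' normalises by its spot count. The pipeline: (1) PCA of the normalized
#' layer; (2) retain only principal components whose eigenvalue exceeds 1.5
#' times the median of the leading 30 eigenvalues — the median estimates the
#' isotropic noise floor, so the retained components carry regional signal
#' and k-means cannot profitably split pure noise; (3) estimate the
#' within-region noise scale as the median squared residual of a k-means
#' fit with d + 1 clusters (d = retained components; d + 1 is the smallest
#' region count consistent with d signal dimensions) and set the Potts
#' smoothing weight to twice that scale; (4) segment with
#' [segment_spatial()] at `K = config$het_k_max`; (5) count clusters with
#' at least `config$min_cluster_spots` spots (default 5) and divide by the
#' spot count.
#'
#' @param ds A QC-filtered, normalized [spot_dataset()].
#' @param config Configuration list.
#' @param seed Seed.
#' @return Tibble with `n_clusters_kept`, `n_spots`, `index`.
#' @export
sample_heterogeneity <- function(ds, config = default_config(),
                                 seed = config$seed) {
  stopifnot(inherits(ds, "spot_dataset"))
  graph <- build_spot_graph(ds)
  x <- as.matrix(ds$normalized)
  r <- min(30, nrow(x) - 1, ncol(x))
  pr <- prcomp(x, center = TRUE, scale. = FALSE, rank. = r)
  ev <- pr$sdev[seq_len(r)]^2
  keep <- which(ev > 1.5 * median(ev))
  keep <- keep[keep <= min(config$n_pcs, r)]
  if (length(keep) == 0) keep <- 1L
  pcs <- pr$x[, keep, drop = FALSE]
  rownames(pcs) <- rownames(x)
  K0 <- min(length(keep) + 1L, nrow(pcs) - 1L)
  km <- withr::with_seed(seed, suppressWarnings(
    kmeans(pcs, K0, nstart = 5, iter.max = 50)
  ))
  beta <- config$beta %||%
    (2 * median(rowSums((pcs - km$centers[km$cluster, , drop = FALSE])^2)))
  seg <- segment_spatial(pcs, graph, K = config$het_k_max, beta = beta,
                         max_iter = config$max_iter, seed = seed,
                         n_starts = config$n_starts)
  heterogeneity_index(seg, n_spots = n_spots(ds),
                      min_spots = config$min_cluster_spots)
}

#' Heterogeneity comparison across sample groups
#'
#' Computes the heterogeneity index for every dataset and, when two groups
#' are given, a one-sided Mann-Whitney test that the first group's indices
#' are larger.
#'
#' @param datasets Named list of preprocessed [spot_dataset()]s.
#' @param groups Optional character vector (one group per dataset).
#' @param config Configuration list.
#' @param seed Seed.
#' @return List with `indices` (tibble `sample`, `group`, `index`, ...) and
#'   `test` (tibble or NULL).
#' @export
run_heterogeneity <- function(datasets, groups = NULL,
                              config = default_config(),
                              seed = config$seed) {
  nm <- names(datasets) %||% sprintf("sample_%d", seq_along(datasets))
  idx <- purrr::imap_dfr(setNames(datasets, nm), function(ds, name) {
    dplyr::mutate(sample_heterogeneity(ds, config, seed = seed),
                  sample = name, .before = 1)
  })
  test <- NULL
  if (!is.null(groups)) {
    idx$group <- groups
    gs <- unique(groups)
    if (length(gs) == 2) {
      test <- mann_whitney_u(idx$index[idx$group == gs[1]],
                             idx$index[idx$group == gs[2]],
                             alternative = "greater")
      test$group1 <- gs[1]
      test$group2 <- gs[2]
    }
  }
  list(indices = idx, test = test)
}

#' Nucleus-to-clone assignment and morphology statistics
#'
#' Builds clone territories from a clone map, assigns nuclei by centroid,
#' compares nuclear areas between clones, and (when FISH counts are given)
#' validates the mapping against per-nucleus probe counts.
#'
#' @param clone_map A [map_clones()] result.
#' @param graph The spot graph used for mapping.
#' @param nuclei Nucleus tibble.
#' @param fish Optional FISH count tibble.
#' @param config Configuration list.
#' @return List with `territories`, `nuclei` (assigned), `area_stats`,
#'   `fish_validation` (or NULL).
#' @export
run_nuclei <- function(clone_map, graph, nuclei, fish = NULL,
                       config = default_config()) {
  terr <- clone_territories(clone_map, graph, alpha = config$alpha)
  assigned <- assign_nuclei(nuclei, terr)
  stats <- compare_nuclear_area(assigned)
  fv <- if (!is.null(fish)) validate_with_fish(assigned, fish)
  list(territories = terr, nuclei = assigned, area_stats = stats,
       fish_validation = fv)
}

#' Microtube quantification from a structure table
#'
#' Applies the area filters and computes per-crop and per-sample microtube
#' area per cell.
#'
#' @param structures Structure tibble or path to a structures CSV.
#' @param config Configuration list.
#' @return List with `filtered`, `per_crop`, `per_sample`.
#' @export
run_microtubes <- function(structures, config = default_config()) {
  if (is.character(structures)) structures <- read_structures(structures)
  filtered <- filter_structures(structures,
                                cell_min = config$cell_min_area_um2,
                                mt_min = config$microtube_min_area_um2)
  quant <- microtube_area_per_cell(filtered,
                                   aggregate = config$crop_aggregate)
  list(filtered = filtered, per_crop = quant$per_crop,
       per_sample = quant$per_sample)
}

#' End-to-end run on a synthetic sample
#'
#' Simulates a sample to disk, reads it back, and runs every stage: QC,
#' clone mapping (with accuracy against the simulated truth), clone
#' territories, nucleus assignment and area statistics, FISH validation,
#' heterogeneity index, and microtube quantification on a simulated
#' structure table. The report is written as JSON when `report_path` is
#' given and regenerates deterministically from (config, seed).
#'
#' @param out_dir Working directory for the sample files.
#' @param config Configuration list.
#' @param seed Seed overriding `config$seed`.
#' @param report_path Optional path for the JSON report.
#' @return The report list (invisibly writes JSON when requested).
#' @export
run_full <- function(out_dir, config = default_config(),
                     seed = config$seed, report_path = NULL) {
  sample_dir <- file.path(out_dir, "sample")
  run_simulate(sample_dir, config, seed = seed)
  mapping <- run_clone_mapping(sample_dir, config, seed = seed)
  nuclei <- read_nuclei(file.path(sample_dir, "nuclei.csv"))
  fish <- readr::read_csv(file.path(sample_dir, "fish_counts.csv"),
                          show_col_types = FALSE)
  nuc <- run_nuclei(mapping$clone_map, mapping$graph, nuclei, fish, config)
  het <- sample_heterogeneity(mapping$dataset, config, seed = seed)
  structures <- simulate_structure_table(seed = seed + 5L)
  mt <- run_microtubes(structures, config)

  report <- list(
    software = list(package = "spotclone",
                    version = as.character(utils::packageVersion("spotclone"))),
    seed = seed,
    config = config,
    qc = mapping$qc_state,
    clone_mapping = list(
      n_spots = nrow(mapping$clone_map$assignments),
      clone_sizes = as.list(table(mapping$clone_map$assignments$clone)),
      concordance_with_control = mapping$clone_map$concordance,
      accuracy = if (!is.null(mapping$accuracy)) mapping$accuracy$accuracy
    ),
    heterogeneity = as.list(het),
    nuclear_morphology = as.list(nuc$area_stats),
    fish_validation = list(
      tests = nuc$fish_validation$tests,
      distribution = nuc$fish_validation$distribution
    ),
    territories = lapply(unclass(nuc$territories), function(t) {
      list(clone = t$clone, n_spots = length(t$spots),
           hull_area_um2 = t$hull$area,
           rings = lapply(t$hull$rings, function(r) unname(as.matrix(r))))
    }),
    microtubes = list(per_crop = mt$per_crop, per_sample = mt$per_sample)
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  report
}
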