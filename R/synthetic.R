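#' Simulation parameters for synthetic spot samples
#'
#' Bundles the parameters of the synthetic Visium-style sample generator.
#' Counts follow a negative binomial with mean
#' `mu(s, g) = L_s * beta_g * ((1 - c) * d[clone(s), g] + c)` and variance
#' `mu + mu^2 / theta` (so `nb_dispersion` is the NB size parameter theta;
#' larger theta means closer to Poisson). `L_s` is a lognormal per-spot
#' library-size factor, `beta_g` a lognormal per-gene baseline, `d` the
#' copy-number dosage multiplier (copy number / ploidy) and `c` the
#' normal-cell contamination fraction. Contamination is modelled as a mixture
#' on the mean (a fraction `c` of each spot's signal is dosage-neutral), not
#' as a mixture of whole counts, which keeps the clone contrast in closed
#' form: the expected informative-gene ratio between clones with dosage `d`
#' vs 1 is `((1 - c) * d + c) / 1` when the reference clone is diploid.
#'
#' @param n_rows,n_cols Lattice dimensions (rows x columns), both >= 2.
#' @param spacing_um Center-to-center spot spacing in micrometres. The
#'   default 100 is the standard spacing of hexagonally packed 55-um spots.
#' @param n_genes Number of genes.
#' @param baseline_mean Median per-gene expected count per spot (scale of
#'   `beta_g`).
#' @param gene_logmean_sd Log-scale standard deviation of per-gene baselines.
#' @param nb_dispersion NB size parameter theta (> 0).
#' @param libsize_sd Log-scale standard deviation of per-spot size factors.
#' @param contamination Fraction in \[0, 1\] of dosage-neutral (normal-cell)
#'   signal per spot.
#' @param layout Clone field layout: `"half_split"` (clone A occupies the
#'   left half of the columns) or `"blob"` (thresholded sign of seeded
#'   Gaussian-smoothed noise).
#' @param blob_smooth_um Gaussian smoothing bandwidth (um) for the blob
#'   layout.
#' @param seed Integer seed; every generator derives its stream from it.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_rows = 40, n_cols = 40, spacing_um = 100,
                       n_genes = 2000, baseline_mean = 0.5,
                       gene_logmean_sd = 1, nb_dispersion = 2,
                       libsize_sd = 0.3, contamination = 0.2,
                       layout = c("half_split", "blob"),
                       blob_smooth_um = 300, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(n_rows >= 2, n_cols >= 2, spacing_um > 0, n_genes >= 1,
            baseline_mean > 0, nb_dispersion > 0, libsize_sd >= 0,
            gene_logmean_sd >= 0, blob_smooth_um > 0)
  if (contamination < 0 || contamination > 1) {
    abort("contamination must be in [0, 1]")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         spacing_um = spacing_um, n_genes = as.integer(n_genes),
         baseline_mean = baseline_mean, gene_logmean_sd = gene_logmean_sd,
         nb_dispersion = nb_dispersion, libsize_sd = libsize_sd,
         contamination = contamination, layout = layout,
         blob_smooth_um = blob_smooth_um, seed = as.integer(seed)),
    class = "sim_params"
  )
}

# Hexagonal offset lattice: odd array rows shifted right by spacing/2, rows
# spaced spacing * sqrt(3)/2 apart, so all six neighbours are at distance
# `spacing`.
hex_lattice <- function(params) {
  g <- expand.grid(array_col = seq_len(params$n_cols) - 1L,
                   array_row = seq_len(params$n_rows) - 1L)
  tibble(
    spot_id = sprintf("spot_%05d", seq_len(nrow(g))),
    array_row = as.integer(g$array_row),
    array_col = as.integer(g$array_col),
    x_um = g$array_col * params$spacing_um +
      (g$array_row %% 2) * params$spacing_um / 2,
    y_um = g$array_row * params$spacing_um * sqrt(3) / 2
  )
}

#' Generate a two-clone spatial label field on a hexagonal lattice
#'
#' For `layout = "half_split"` clone A occupies array columns
#' `< n_cols / 2`. For `layout = "blob"`, iid Gaussian noise on the lattice
#' is smoothed with a Gaussian kernel of bandwidth `blob_smooth_um` and
#' labels are the sign of the smoothed field (A where positive); if either
#' clone comes out empty the draw is repeated with incremented seeds (up to
#' 10 attempts) before failing.
#'
#' @param params A [sim_params()].
#' @return Tibble (class `clone_field`) with columns `spot_id`, `array_row`,
#'   `array_col`, `x_um`, `y_um`, `clone` and attribute `spacing_um`.
#' @export
generate_clone_field <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  lat <- hex_lattice(params)
  if (params$layout == "half_split") {
    clone <- ifelse(lat$array_col < params$n_cols / 2, "A", "B")
  } else {
    clone <- NULL
    for (attempt in 0:9) {
      z <- withr::with_seed(params$seed + attempt, rnorm(nrow(lat)))
      d2 <- as.matrix(dist(cbind(lat$x_um, lat$y_um)))^2
      w <- exp(-d2 / (2 * params$blob_smooth_um^2))
      sm <- as.vector(w %*% z) / rowSums(w)
      cand <- ifelse(sm > 0, "A", "B")
      if (length(unique(cand)) == 2L) {
        clone <- cand
        break
      }
    }
    if (is.null(clone)) abort("blob layout produced an empty clone in 10 attempts")
  }
  out <- lat
  out$clone <- clone
  attr(out, "spacing_um") <- params$spacing_um
  class(out) <- c("clone_field", class(out))
  out
}

#' Construct the ground truth for a two-clone synthetic sample
#'
#' Picks `n_informative` clone-informative genes, places them on two
#' synthetic chromosomes (`"chr8"`, `"chr12"`) with whole-chromosome
#' copy-number differences between the clones (copy number `cn_gain` in
#' clone A vs `cn_base` in clone B), puts the remaining genes on `"chr1"`
#' (diploid in both clones), and records the per-clone dosage multiplier
#' `copy_number / ploidy` for every gene. The returned object carries the
#' matching gene annotation and clone CNV profile tables so the whole
#' pipeline (informative-gene selection included) can run on synthetic data.
#'
#' @param params A [sim_params()].
#' @param n_informative Number of clone-informative genes.
#' @param cn_gain,cn_base Copy numbers of the informative regions in clone A
#'   (the daughter, gained clone) and clone B (the ancestral clone).
#' @param ploidy Baseline ploidy (default 2).
#'
#' @return A list of class `synthetic_truth` with elements `params`,
#'   `clone_field`, `gene_dosage` (clone x gene multiplier matrix),
#'   `informative_genes`, `annotation`, `cnv_profiles`.
#' @export
make_synthetic_truth <- function(params, n_informative = 200, cn_gain = 4,
                                 cn_base = 2, ploidy = 2) {
  stopifnot(inherits(params, "sim_params"),
            n_informative >= 1, n_informative <= params$n_genes,
            cn_gain >= 0, cn_base >= 0, cn_gain != cn_base)
  field <- generate_clone_field(params)
  genes <- sprintf("gene_%05d", seq_len(params$n_genes))
  informative <- withr::with_seed(
    params$seed + 1L, sort(sample(genes, n_informative))
  )
  # split informative genes over the two synthetic CNV chromosomes
  half <- ceiling(n_informative / 2)
  chrom <- setNames(rep("chr1", params$n_genes), genes)
  chrom[informative[seq_len(half)]] <- "chr8"
  chrom[informative[-seq_len(half)]] <- "chr12"
  ann <- tibble(gene_id = genes, chromosome = unname(chrom)) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(start = (dplyr::row_number() - 1L) * 10000L,
                  end = .data$start + 1000L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$gene_id)
  chr_len <- 1e9
  profiles <- dplyr::bind_rows(
    tibble(clone = "A",
           chromosome = c("chr1", "chr8", "chr12"),
           start = 0, end = chr_len,
           copy_number = c(ploidy, cn_gain, cn_gain)),
    tibble(clone = "B",
           chromosome = c("chr1", "chr8", "chr12"),
           start = 0, end = chr_len,
           copy_number = c(ploidy, cn_base, cn_base))
  )
  dosage <- matrix(1, nrow = 2, ncol = params$n_genes,
                   dimnames = list(c("A", "B"), genes))
  dosage["A", informative] <- cn_gain / ploidy
  dosage["B", informative] <- cn_base / ploidy
  structure(
    list(params = params, clone_field = field, gene_dosage = dosage,
         informative_genes = informative, annotation = ann,
         cnv_profiles = profiles),
    class = "synthetic_truth"
  )
}

#' Generate a multi-region label field (Voronoi partition of the lattice)
#'
#' Used to emulate tissues composed of a chosen number of transcriptionally
#' distinct regions (for heterogeneity-index experiments). `n_regions`
#' seed spots are sampled and every spot is labelled by its nearest seed,
#' which yields contiguous regions.
#'
#' @param params A [sim_params()].
#' @param n_regions Number of regions (>= 1).
#' @param seed Seed; defaults to `params$seed`.
#' @return A labelled field tibble as in [generate_clone_field()], with
#'   labels `region_1 ... region_k`.
#' @export
generate_region_field <- function(params, n_regions, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"), n_regions >= 1)
  lat <- hex_lattice(params)
  if (n_regions > nrow(lat)) abort("more regions than spots")
  centers <- withr::with_seed(seed, sample(nrow(lat), n_regions))
  d2 <- outer(lat$x_um, lat$x_um[centers], "-")^2 +
    outer(lat$y_um, lat$y_um[centers], "-")^2
  lab <- max.col(-d2, ties.method = "first")
  out <- lat
  out$clone <- sprintf("region_%d", lab)
  attr(out, "spacing_um") <- params$spacing_um
  class(out) <- c("clone_field", class(out))
  out
}

#' Ground truth for a multi-region expression sample
#'
#' Every region gets an independent lognormal expression multiplier per gene
#' (`exp(N(0, region_effect_sd))`), feeding the same negative-binomial count
#' model as the two-clone truth.
#'
#' @param params A [sim_params()].
#' @param n_regions Number of regions.
#' @param region_effect_sd Log-scale SD of per-region gene multipliers.
#' @param seed Seed; defaults to `params$seed`.
#' @return A `synthetic_truth` whose `gene_dosage` has one row per region.
#' @export
make_region_truth <- function(params, n_regions, region_effect_sd = 0.5,
                              seed = params$seed) {
  field <- generate_region_field(params, n_regions, seed = seed)
  genes <- sprintf("gene_%05d", seq_len(params$n_genes))
  labels <- sort(unique(field$clone))
  mult <- withr::with_seed(
    seed + 1L,
    matrix(exp(rnorm(length(labels) * params$n_genes, 0, region_effect_sd)),
           nrow = length(labels), dimnames = list(labels, genes))
  )
  structure(
    list(params = params, clone_field = field, gene_dosage = mult,
         informative_genes = character(), annotation = NULL,
         cnv_profiles = NULL),
    class = "synthetic_truth"
  )
}

#' Simulate negative-binomial counts for a synthetic truth
#'
#' Draws `count(s, g) ~ NB(mean = L_s * beta_g * ((1 - c) * d[label(s), g] +
#' c), size = theta)`; see [sim_params()] for the model.
#'
#' @param truth A [make_synthetic_truth()] / [make_region_truth()] object.
#' @return A [spot_dataset()] whose barcodes are the truth's spot ids.
#' @export
simulate_counts <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  p <- truth$params
  field <- truth$clone_field
  genes <- colnames(truth$gene_dosage)
  n <- nrow(field)
  G <- length(genes)
  withr::with_seed(p$seed + 2L, {
    beta_g <- p$baseline_mean * exp(rnorm(G, 0, p$gene_logmean_sd))
    L_s <- exp(rnorm(n, 0, p$libsize_sd))
    d <- truth$gene_dosage[field$clone, , drop = FALSE]
    mu <- (L_s %o% beta_g) * ((1 - p$contamination) * d + p$contamination)
    if (max(mu) > .Machine$integer.max / 16) {
      abort("simulated means exceed the supported integer range")
    }
    cnt <- matrix(rnbinom(n * G, mu = as.vector(mu), size = p$nb_dispersion),
                  nrow = n, dimnames = list(field$spot_id, genes))
  })
  pos <- tibble(barcode = field$spot_id, in_tissue = 1L,
                array_row = field$array_row, array_col = field$array_col,
                x_um = field$x_um, y_um = field$y_um)
  spot_dataset(cnt, pos)
}

#' Simulate nuclei with clone-dependent areas
#'
#' Nuclei are placed by a homogeneous Poisson process over each spot's disc
#' (radius `spacing / 2`), with lognormal areas parameterised per clone.
#'
#' @param clone_field A labelled field from [generate_clone_field()].
#' @param density_per_mm2 Expected nuclei per square millimetre (> 0; a
#'   vanishingly small value yields an empty table, not an error).
#' @param area_meanlog Named numeric (per clone label) lognormal meanlog of
#'   nuclear areas in um^2.
#' @param area_sdlog Lognormal sdlog (scalar or named per clone).
#' @param seed Integer seed.
#' @return Tibble with `nucleus_id`, `x_um`, `y_um`, `area_um2`,
#'   `true_clone`.
#' @export
simulate_nuclei <- function(clone_field, density_per_mm2,
                            area_meanlog = c(A = log(45), B = log(30)),
                            area_sdlog = 0.35, seed = 1L) {
  stopifnot(inherits(clone_field, "clone_field"))
  if (density_per_mm2 <= 0) abort("density_per_mm2 must be > 0")
  clones <- unique(clone_field$clone)
  if (!all(clones %in% names(area_meanlog))) {
    abort("area_meanlog must name every clone label")
  }
  if (is.null(names(area_sdlog))) {
    area_sdlog <- setNames(rep(area_sdlog[1], length(clones)), clones)
  }
  spacing <- attr(clone_field, "spacing_um") %||%
    min_nonzero_spacing(clone_field$x_um, clone_field$y_um)
  r <- spacing / 2
  lambda <- density_per_mm2 * (pi * r^2) / 1e6   # per-spot disc in mm^2
  withr::with_seed(seed, {
    n_per_spot <- rpois(nrow(clone_field), lambda)
    idx <- rep(seq_len(nrow(clone_field)), n_per_spot)
    n_tot <- length(idx)
    if (n_tot == 0) {
      tibble(nucleus_id = character(), x_um = double(), y_um = double(),
             area_um2 = double(), true_clone = character())
    } else {
      rad <- r * sqrt(runif(n_tot))
      ang <- runif(n_tot, 0, 2 * pi)
      cl <- clone_field$clone[idx]
      area <- exp(rnorm(n_tot, area_meanlog[cl], area_sdlog[cl]))
      tibble(
        nucleus_id = sprintf("nuc_%06d", seq_len(n_tot)),
        x_um = clone_field$x_um[idx] + rad * cos(ang),
        y_um = clone_field$y_um[idx] + rad * sin(ang),
        area_um2 = area,
        true_clone = cl
      )
    }
  })
}

#' Simulate FISH-style probe counts per nucleus
#'
#' Each observed count is `Binomial(copy_number, efficiency)` true signals
#' plus `Poisson(false_rate)` spurious ones, per nucleus and probe.
#'
#' @param nuclei Nucleus tibble with a `true_clone` (or `clone`) column.
#' @param probe_cn_per_clone Named list: probe name -> named copy-number
#'   vector per clone, e.g. `list(cen8 = c(A = 4, B = 2))`.
#' @param efficiency Hybridisation efficiency in \[0, 1\].
#' @param false_rate Mean number of spurious signals per nucleus.
#' @param seed Integer seed.
#' @return Tibble with `nucleus_id`, `probe`, `count`.
#' @export
simulate_fish_counts <- function(nuclei, probe_cn_per_clone,
                                 efficiency = 0.9, false_rate = 0.05,
                                 seed = 1L) {
  if (efficiency < 0 || efficiency > 1) abort("efficiency must be in [0, 1]")
  if (false_rate < 0) abort("false_rate must be >= 0")
  cl <- nuclei$true_clone %||% nuclei$clone
  if (is.null(cl)) abort("nuclei need a true_clone or clone column")
  withr::with_seed(seed, {
    purrr::imap_dfr(probe_cn_per_clone, function(cn, probe) {
      if (any(cn < 0)) abort("probe copy numbers must be >= 0")
      if (!all(unique(cl) %in% names(cn))) {
        abort(paste0("probe ", probe, " lacks a copy number for some clone"))
      }
      tibble(
        nucleus_id = nuclei$nucleus_id,
        probe = probe,
        count = rbinom(length(cl), cn[cl], efficiency) +
          rpois(length(cl), false_rate)
      )
    })
  })
}

#' Simulate a microtube structure table
#'
#' Emulates the tabular output of pixel-classification of fixed-size image
#' crops (400 x 400 um): per crop, `counts_per_crop["cell"]` structures of
#' class `cell` and `counts_per_crop["microtube"]` of class `microtube`,
#' with areas drawn from the supplied generators.
#'
#' @param n_crops Number of crops.
#' @param cell_area_dist,mt_area_dist Functions `f(n)` returning `n` areas
#'   (um^2).
#' @param counts_per_crop Named integer vector with elements `cell` and
#'   `microtube`.
#' @param seed Integer seed.
#' @param sample_id Sample identifier stored in the table.
#' @return Tibble with `sample_id`, `crop_id`, `class`, `area_um2` and
#'   attribute `crop_um = 400`.
#' @export
simulate_structure_table <- function(n_crops = 3,
                                     cell_area_dist = function(n)
                                       exp(rnorm(n, log(60), 0.5)),
                                     mt_area_dist = function(n)
                                       exp(rnorm(n, log(8), 0.6)),
                                     counts_per_crop = c(cell = 100,
                                                         microtube = 40),
                                     seed = 1L, sample_id = "sample_1") {
  stopifnot(n_crops >= 1, all(counts_per_crop >= 0),
            is.function(cell_area_dist), is.function(mt_area_dist))
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(n_crops), function(crop) {
      dplyr::bind_rows(
        tibble(class = "cell",
               area_um2 = cell_area_dist(counts_per_crop[["cell"]])),
        tibble(class = "microtube",
               area_um2 = mt_area_dist(counts_per_crop[["microtube"]]))
      ) |>
        dplyr::mutate(sample_id = sample_id, crop_id = crop,
                      .before = 1)
    })
  })
  if (any(out$area_um2 <= 0)) abort("area generators must return areas > 0")
  attr(out, "crop_um") <- 400
  out
}

min_nonzero_spacing <- function(x, y) {
  d <- dist(cbind(x, y))
  min(d[d > 0])
}
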