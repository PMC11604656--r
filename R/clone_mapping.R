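#' Select clone-informative genes from CNV profiles
#'
#' Returns the genes whose annotated interval overlaps (any overlap) a
#' genomic region where the two clones' copy numbers differ. Copy number
#' outside listed intervals defaults to the profiles' ploidy. When the
#' profiles are given at whole-chromosome resolution this reduces to all
#' genes on the chromosomes that differ between clones (for the human
#' medulloblastoma clones, all genes on chromosomes 8 and 12).
#'
#' @param annotation Gene annotation tibble (`gene_id`, `chromosome`,
#'   `start`, `end`; 0-based half-open).
#' @param profiles CNV profile tibble with exactly two clones (`clone`,
#'   `chromosome`, `start`, `end`, `copy_number`), as from
#'   [read_cnv_profiles()].
#' @param ploidy Baseline ploidy outside listed intervals (default: the
#'   profiles' `ploidy` attribute, else 2).
#' @return Character vector of informative gene ids.
#' @export
select_clone_genes <- function(annotation, profiles, ploidy = NULL) {
  clones <- unique(profiles$clone)
  if (length(clones) != 2) abort("need exactly two clones")
  ploidy <- ploidy %||% attr(profiles, "ploidy") %||% 2

  cn_at <- function(clone, chrom, lo, hi) {
    # piecewise CN of `clone` over breakpoint segments of [lo, hi)
    iv <- profiles[profiles$clone == clone & profiles$chromosome == chrom, ]
    function(a, b) {
      hit <- iv$start < b & iv$end > a
      if (!any(hit)) ploidy else iv$copy_number[which(hit)[1]]
    }
  }
  diff_regions <- function(chrom) {
    iv <- profiles[profiles$chromosome == chrom, ]
    bp <- sort(unique(c(0, iv$start, iv$end, Inf)))
    f1 <- cn_at(clones[1], chrom, 0, Inf)
    f2 <- cn_at(clones[2], chrom, 0, Inf)
    segs <- list()
    for (i in seq_len(length(bp) - 1)) {
      a <- bp[i]; b <- bp[i + 1]
      if (f1(a, b) != f2(a, b)) segs[[length(segs) + 1]] <- c(a, b)
    }
    segs
  }

  chroms <- unique(c(profiles$chromosome, annotation$chromosome))
  keep <- logical(nrow(annotation))
  any_diff <- FALSE
  for (chrom in chroms) {
    segs <- diff_regions(chrom)
    if (length(segs) == 0) next
    any_diff <- TRUE
    on_chrom <- annotation$chromosome == chrom
    for (seg in segs) {
      keep <- keep | (on_chrom & annotation$start < seg[2] &
                        annotation$end > seg[1])
    }
  }
  if (!any_diff) abort("clones are indistinguishable: no differing CNV region")
  annotation$gene_id[keep]
}

#' Per-spot clone score
#'
#' The mean normalized expression over the clone-informative gene set. Only
#' genes present in the dataset (i.e. surviving QC) contribute.
#'
#' @param ds A [spot_dataset()] with a normalized layer.
#' @param gene_set Character vector of gene ids (non-empty intersection with
#'   the dataset's genes required).
#' @return Tibble with `spot_id`, `clone_score`.
#' @export
compute_clone_score <- function(ds, gene_set) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (is.null(ds$normalized)) abort("normalized layer missing")
  if (length(gene_set) == 0) abort("empty gene set")
  genes <- intersect(gene_set, colnames(ds$normalized))
  if (length(genes) == 0) abort("no informative gene present in the dataset")
  tibble(spot_id = rownames(ds$normalized),
         clone_score = unname(Matrix::rowSums(
           ds$normalized[, genes, drop = FALSE])) / length(genes))
}

#' Map genetic clones onto spots
#'
#' The clone-mapping procedure: (1) restrict the normalized expression to
#' the clone-informative gene set (from the CNV profiles, QC-surviving genes
#' only); (2) run the spatially smoothed segmentation ([segment_spatial()])
#' with exactly two clusters on those features; (3) assign polarity by the
#' mean clone score: the cluster with the higher mean informative-gene
#' expression is called the gain clone A (the more recent daughter clone;
#' the lower-dosage cluster is the ancestral clone B) — set
#' `invert_polarity = TRUE` when the differing regions are losses; (4) run
#' the non-spatial control clustering ([cluster_expression()], forced to two
#' communities) on the same features and record per-spot concordance.
#'
#' @param ds A QC-filtered [spot_dataset()] with a normalized layer.
#' @param annotation Gene annotation tibble.
#' @param profiles Two-clone CNV profile tibble.
#' @param graph Optional [build_spot_graph()]; built from the dataset's
#'   positions when `NULL`.
#' @param beta,max_iter,seed,n_starts Passed to [segment_spatial()].
#' @param knn,n_pcs Passed to the control [cluster_expression()].
#' @param invert_polarity Call the lower-scoring cluster A (loss regions).
#' @return An object of class `clone_map`: tibble-backed `assignments`
#'   (`spot_id`, `clone`, `clone_score`, `margin`,
#'   `concordant_with_control`), plus `concordance`, `gene_set`,
#'   `segmentation`, `control`, `params`.
#' @export
map_clones <- function(ds, annotation, profiles, graph = NULL, beta = NULL,
                       max_iter = 100, seed = 1L, n_starts = 5L, knn = 15,
                       n_pcs = 20, invert_polarity = FALSE) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (is.null(ds$normalized)) abort("normalized layer missing")
  gene_set <- select_clone_genes(annotation, profiles)
  genes <- intersect(gene_set, colnames(ds$normalized))
  if (length(genes) == 0) abort("no informative gene survived QC")
  features <- as.matrix(ds$normalized[, genes, drop = FALSE])
  graph <- graph %||% build_spot_graph(ds)

  seg <- segment_spatial(features, graph, K = 2, beta = beta,
                         max_iter = max_iter, seed = seed,
                         n_starts = n_starts)
  if (seg$K < 2) abort("segmentation collapsed to a single cluster")
  scores <- compute_clone_score(ds, genes)
  scores <- scores[match(seg$labels$spot_id, scores$spot_id), ]
  mean_by_cluster <- tapply(scores$clone_score, seg$labels$cluster, mean)
  if (length(mean_by_cluster) < 2 ||
      abs(diff(range(mean_by_cluster))) < 1e-9) {
    abort("clone polarity undecidable: cluster mean scores are equal")
  }
  gain_cluster <- as.integer(names(which.max(mean_by_cluster)))
  if (invert_polarity) gain_cluster <- setdiff(c(1L, 2L), gain_cluster)
  clone <- ifelse(seg$labels$cluster == gain_cluster, "A", "B")

  # per-spot confidence: margin between squared distances to the two
  # cluster centroids (positive = closer to own centroid)
  d2 <- sq_dist_to_centroids(features, seg$centroids)
  own <- d2[cbind(seq_len(nrow(d2)), seg$labels$cluster)]
  other <- d2[cbind(seq_len(nrow(d2)), 3L - seg$labels$cluster)]
  margin <- other - own

  control <- cluster_expression(features, k_neighbors = knn,
                                seed = seed, n_pcs = n_pcs, K_target = 2)
  conc <- concordance(seg$labels$cluster, control$labels$cluster)
  # align control labels to the spatial ones for the per-spot flag
  agree_direct <- mean(seg$labels$cluster == control$labels$cluster)
  ctrl <- control$labels$cluster
  if (agree_direct < 0.5) ctrl <- 3L - ctrl
  structure(
    list(assignments = tibble(
           spot_id = seg$labels$spot_id, clone = clone,
           clone_score = scores$clone_score, margin = margin,
           concordant_with_control = seg$labels$cluster == ctrl),
         concordance = conc, gene_set = genes, segmentation = seg,
         control = control,
         params = list(seed = seed, beta = seg$params$beta,
                       invert_polarity = invert_polarity,
                       n_informative_used = length(genes))),
    class = "clone_map"
  )
}

#' @export
print.clone_map <- function(x, ...) {
  tab <- table(x$assignments$clone)
  cat("<clone_map> ", nrow(x$assignments), " spots (",
      paste(names(tab), tab, sep = ": ", collapse = ", "), ")\n", sep = "")
  cat("  informative genes used: ", x$params$n_informative_used, "\n",
      sep = "")
  cat("  concordance with non-spatial control: ",
      round(x$concordance, 4), "\n", sep = "")
  invisible(x)
}

#' Agreement of two 2-cluster labelings
#'
#' The maximum, over the two possible label pairings, of the fraction of
#' spots on which the labelings agree; invariant to swapping labels.
#'
#' @param labels1,labels2 Equal-length label vectors with at most two
#'   distinct values each.
#' @return Fraction in \[0.5, 1\] (for two balanced labels).
#' @export
concordance <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) abort("labelings differ in length")
  if (length(unique(labels1)) > 2 || length(unique(labels2)) > 2) {
    abort("concordance is defined for 2-label clusterings")
  }
  u2 <- unique(labels2)
  agree <- mean(labels1 == labels2)
  if (length(u2) == 2) {
    swapped <- ifelse(labels2 == u2[1], u2[2], u2[1])
    agree <- max(agree, mean(labels1 == swapped))
  }
  agree
}

#' Validate a clone map against FISH-style per-nucleus probe counts
#'
#' For every clone territory and probe, tabulates the empirical signal-count
#' distribution (fractions of nuclei with 0, 1, 2, 3 and 4+ signals) and
#' compares the count distributions between clone-A and clone-B nuclei with
#' a two-sided Mann-Whitney test per probe. With fewer than 2 nuclei in a
#' clone for a probe the comparison is flagged unreliable (`p = NA`).
#'
#' @param nuclei Nucleus tibble with a `clone` assignment column (from
#'   [assign_nuclei()]); unassigned nuclei are dropped.
#' @param fish FISH count tibble (`nucleus_id`, `probe`, `count`).
#' @return List of class `fish_validation`: `distribution` (tibble `clone`,
#'   `probe`, `signals`, `n`, `fraction`) and `tests` (tibble `probe`, `U`,
#'   `p`, `n_A`, `n_B`, `reliable`).
#' @export
validate_with_fish <- function(nuclei, fish) {
  stopifnot(all(c("nucleus_id", "clone") %in% names(nuclei)),
            all(c("nucleus_id", "probe", "count") %in% names(fish)))
  if (anyDuplicated(fish[c("nucleus_id", "probe")])) {
    abort("duplicate (nucleus, probe) pair in FISH table")
  }
  dat <- dplyr::inner_join(fish,
                           nuclei[c("nucleus_id", "clone")],
                           by = "nucleus_id") |>
    dplyr::filter(.data$clone %in% c("A", "B"))
  if (nrow(dat) == 0) abort("no FISH count falls in an assigned clone area")
  if (length(unique(dat$clone)) < 2) {
    abort("a clone area has no nuclei with FISH counts")
  }
  distribution <- dat |>
    dplyr::mutate(signals = ifelse(.data$count >= 4, "4+",
                                   as.character(.data$count))) |>
    dplyr::count(.data$clone, .data$probe, .data$signals, name = "n") |>
    dplyr::group_by(.data$clone, .data$probe) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  tests <- dat |>
    dplyr::group_by(.data$probe) |>
    dplyr::group_modify(function(d, key) {
      a <- d$count[d$clone == "A"]
      b <- d$count[d$clone == "B"]
      reliable <- length(a) >= 2 && length(b) >= 2
      if (reliable) {
        mw <- mann_whitney_u(a, b, "two_sided")
        tibble(U = mw$U, p = mw$p, n_A = length(a), n_B = length(b),
               reliable = TRUE)
      } else {
        tibble(U = NA_real_, p = NA_real_, n_A = length(a),
               n_B = length(b), reliable = FALSE)
      }
    }) |>
    dplyr::ungroup()
  structure(list(distribution = distribution, tests = tests),
            class = "fish_validation")
}

#' @export
print.fish_validation <- function(x, ...) {
  cat("<fish_validation>\n")
  print(x$tests)
  invisible(x)
}

#' Accuracy of clone assignments against a known truth
#'
#' Fraction of spots whose inferred clone matches the true label, maximised
#' over the two clone-label pairings (the clone names themselves carry
#' polarity, so the direct agreement is also reported).
#'
#' @param clone_map A [map_clones()] result.
#' @param true_labels Named character vector (spot id -> true clone).
#' @return Tibble with `accuracy` (direct, polarity-aware) and
#'   `accuracy_best_pairing`.
#' @export
clone_accuracy <- function(clone_map, true_labels) {
  a <- clone_map$assignments
  truth <- true_labels[a$spot_id]
  if (anyNA(truth)) abort("truth does not cover all mapped spots")
  direct <- mean(a$clone == truth)
  tibble(accuracy = direct,
         accuracy_best_pairing = concordance(a$clone, truth))
}
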