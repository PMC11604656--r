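#' Spatial heterogeneity index of a segmentation
#'
#' The number of clusters containing at least `min_spots` spots, divided by
#' the number of spots in the sample. Small clusters (fewer than 5 spots by
#' default) are excluded from the numerator; the index is invariant to
#' cluster relabeling.
#'
#' @param segmentation A [segment_spatial()] result, or a vector of cluster
#'   labels (one per spot).
#' @param n_spots Number of spots normalising the index; defaults to the
#'   number of labelled spots.
#' @param min_spots Minimum cluster size counted (default 5).
#' @return Tibble with `n_clusters_kept`, `n_spots`, `index`.
#' @export
heterogeneity_index <- function(segmentation, n_spots = NULL, min_spots = 5) {
  labels <- if (inherits(segmentation, "segmentation_result")) {
    segmentation$labels$cluster
  } else {
    segmentation
  }
  n_spots <- n_spots %||% length(labels)
  if (n_spots == 0) abort("n_spots must be positive")
  sizes <- table(labels)
  kept <- sum(sizes >= min_spots)
  tibble(n_clusters_kept = kept, n_spots = as.integer(n_spots),
         index = kept / n_spots)
}

#' Fraction of variance explained by spatial regions
#'
#' An R-squared of region membership: `1 - SS_within / SS_total`, where
#' `SS_within` pools squared deviations around region means. Lies in
#' \[0, 1\], is invariant to affine transforms of the values, and measures
#' how much of a gene's variance is attributable to the spatial makeup of
#' the tissue as captured by a segmentation.
#'
#' @param values Numeric vector, one value per spot (non-constant).
#' @param segmentation Segmentation result or label vector aligned with
#'   `values`.
#' @return A fraction in \[0, 1\].
#' @export
spatial_variance_fraction <- function(values, segmentation) {
  labels <- if (inherits(segmentation, "segmentation_result")) {
    segmentation$labels$cluster
  } else {
    segmentation
  }
  stopifnot(length(values) == length(labels))
  if (max(values) == min(values)) abort("values are constant")
  ss_total <- sum((values - mean(values))^2)
  ss_within <- sum(unlist(tapply(values, labels,
                                 function(v) sum((v - mean(v))^2))))
  1 - ss_within / ss_total
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, with `z` the centered
#' values and `w` the row-normalized adjacency weights of the spot graph.
#' Under random permutation of the values, `E[I] = -1 / (n - 1)`.
#'
#' @param values Numeric vector aligned with `graph$nodes` (non-constant).
#' @param graph A [build_spot_graph()] object.
#' @return Moran's I.
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "spot_graph"))
  if (length(values) != length(graph$nodes)) {
    abort("values must align with graph nodes")
  }
  if (max(values) == min(values)) abort("Moran's I undefined for constant values")
  as.vector(morans_i_matrix(matrix(values, ncol = 1), graph))
}

# vectorized Moran's I over columns of a matrix (rows aligned with nodes)
morans_i_matrix <- function(x, graph) {
  w <- row_normalized_weights(graph)
  n <- nrow(x)
  s0 <- sum(w)
  z <- sweep(x, 2, colMeans(x))
  num <- colSums(z * as.matrix(w %*% z))
  den <- colSums(z^2)
  (n / s0) * num / den
}

#' Mann-Whitney U test
#'
#' Exact p-value by enumeration of rank configurations when
#' `length(x) + length(y) <= 16` and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction. `U` is the
#' number of (x, y) pairs with `x > y` (+ half the ties).
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (for the
#'   location of `x` relative to `y`).
#' @return Tibble with `U`, `p`, `method`.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0 || length(y) == 0) abort("empty sample")
  alt <- sub("two_sided", "two.sided", alternative)
  exact <- (length(x) + length(y) <= 16) &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = exact, correct = TRUE)
  )
  # wilcox.test's W equals U for x vs y; all-tied degenerate case gives z=0
  p <- ht$p.value
  if (is.nan(p)) p <- 1
  tibble(U = unname(ht$statistic), p = p,
         method = if (exact) "exact" else "normal_approx")
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= hits_in_set)` for
#' `X ~ Hypergeometric(universe, hits_total, set_size)`: the probability of
#' seeing at least the observed overlap between a drawn set of size
#' `set_size` and `hits_total` marked elements of a universe. Computed via
#' the log-space tail of the hypergeometric distribution, so tiny p-values
#' do not underflow.
#'
#' @param hits_in_set Observed overlap.
#' @param set_size Size of the drawn set.
#' @param hits_total Number of marked elements in the universe.
#' @param universe Universe size.
#' @param log.p Return log(p) instead of p.
#' @return The (log) p-value.
#' @export
hypergeometric_enrichment <- function(hits_in_set, set_size, hits_total,
                                      universe, log.p = FALSE) {
  if (hits_in_set > min(set_size, hits_total) ||
      any(c(hits_in_set, set_size, hits_total) > universe) ||
      any(c(hits_in_set, set_size, hits_total, universe) < 0)) {
    abort("inconsistent hypergeometric counts")
  }
  if (hits_in_set == 0) return(if (log.p) 0 else 1)
  lp <- phyper(hits_in_set - 1, hits_total, universe - hits_total, set_size,
               lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment `q_(i) = min_(j >= i) p_(j) * n / j`, mapped back
#' to the input order and capped at 1.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must be in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}
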