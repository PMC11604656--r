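#' Filter spots by total counts and detected genes
#'
#' Retains spots with total counts `>= min_counts` and number of detected
#' genes (count > 0) `>= min_genes`; thresholds are recorded in `qc_state`.
#'
#' @param ds A [spot_dataset()].
#' @param min_counts,min_genes Non-negative thresholds.
#' @return Filtered [spot_dataset()].
#' @export
filter_spots <- function(ds, min_counts = 0, min_genes = 0) {
  stopifnot(inherits(ds, "spot_dataset"), min_counts >= 0, min_genes >= 0)
  totals <- Matrix::rowSums(ds$counts)
  detected <- Matrix::rowSums(ds$counts > 0)
  keep <- totals >= min_counts & detected >= min_genes
  if (!any(keep)) abort("spot filter removed every spot")
  qc <- ds$qc_state
  qc$filter_spots <- list(min_counts = min_counts, min_genes = min_genes,
                          n_removed = sum(!keep))
  spot_dataset(ds$counts[keep, , drop = FALSE], ds$positions,
               normalized = if (!is.null(ds$normalized))
                 ds$normalized[keep, , drop = FALSE],
               qc_state = qc)
}

#' Filter genes by detection rate
#'
#' A gene is kept iff it is detected (count > 0) in at least
#' `min_fraction * n_spots` spots (fraction mode, the human-sample rule:
#' genes detected in less than 10% of spots are removed) or in at least
#' `min_spots` spots (absolute mode, the PDX-sample rule: genes detected in
#' less than 10 spots are removed). Exactly one criterion must be given;
#' the boundary is inclusive (a gene detected in exactly the threshold
#' number of spots is kept).
#'
#' @param ds A [spot_dataset()].
#' @param min_fraction Minimum detection fraction in \[0, 1\].
#' @param min_spots Minimum number of detecting spots.
#' @return Filtered [spot_dataset()].
#' @export
filter_genes <- function(ds, min_fraction = NULL, min_spots = NULL) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (is.null(min_fraction) == is.null(min_spots)) {
    abort("give exactly one of min_fraction or min_spots")
  }
  detected <- Matrix::colSums(ds$counts > 0)
  threshold <- if (!is.null(min_fraction)) {
    stopifnot(min_fraction >= 0, min_fraction <= 1)
    min_fraction * n_spots(ds)
  } else {
    stopifnot(min_spots >= 0)
    min_spots
  }
  keep <- detected >= threshold
  if (!any(keep)) abort("gene filter removed every gene")
  qc <- ds$qc_state
  qc$filter_genes <- list(min_fraction = min_fraction,
                          min_spots = min_spots, n_removed = sum(!keep))
  spot_dataset(ds$counts[, keep, drop = FALSE], ds$positions,
               normalized = if (!is.null(ds$normalized))
                 ds$normalized[, keep, drop = FALSE],
               qc_state = qc)
}

#' Library-size normalization with log transform
#'
#' Adds the normalized layer
#' `log(1 + count * target_sum / spot_total)`; `target_sum` defaults to the
#' median spot total. Spots with zero total must be removed first
#' ([filter_spots()]).
#'
#' @param ds A [spot_dataset()].
#' @param target_sum Target total per spot; `NULL` for the median total.
#' @return The dataset with a `normalized` layer (sparse; zeros stay zero).
#' @export
normalize_log1p <- function(ds, target_sum = NULL) {
  stopifnot(inherits(ds, "spot_dataset"))
  totals <- Matrix::rowSums(ds$counts)
  if (any(totals == 0)) {
    abort("zero-total spot present; run filter_spots first")
  }
  target_sum <- target_sum %||% median(totals)
  scaled <- Diagonal(x = target_sum / totals) %*% ds$counts
  norm <- scaled
  norm@x <- log1p(norm@x)
  qc <- ds$qc_state
  qc$normalize <- list(target_sum = target_sum)
  spot_dataset(ds$counts, ds$positions, normalized = norm, qc_state = qc)
}

#' Rank highly variable genes
#'
#' Ranks genes by the residual of log10 variance around a mean-variance
#' trend: genes are binned into 20 equal-frequency bins of log10 mean (of
#' the normalized layer), the trend is the per-bin running median of log10
#' variance, and residuals are standardized by their median absolute
#' deviation and clipped at `clip`. Deterministic.
#'
#' @param ds A [spot_dataset()] with a normalized layer.
#' @param n_top Number of genes to mark as selected.
#' @param n_bins Number of mean bins for the trend (default 20).
#' @param clip Residual clipping bound in robust SD units.
#' @return Tibble with `gene_id`, `mean`, `variance`, `residual`, `rank`,
#'   `selected`, ordered as the dataset's genes.
#' @export
select_hvg <- function(ds, n_top, n_bins = 20, clip = 10) {
  stopifnot(inherits(ds, "spot_dataset"))
  if (is.null(ds$normalized)) abort("normalized layer missing")
  if (n_top > n_genes(ds)) abort("n_top exceeds the number of genes")
  m <- ds$normalized
  mu <- Matrix::colSums(m) / nrow(m)
  v <- Matrix::colSums(m^2) / nrow(m) - mu^2
  v <- v * nrow(m) / max(1, nrow(m) - 1)
  eps <- 1e-12
  lmu <- log10(mu + eps)
  lv <- log10(v + eps)
  n_bins <- max(1, min(n_bins, length(unique(lmu))))
  bin <- cut(rank(lmu, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  trend <- tapply(lv, bin, median)
  resid <- lv - trend[bin]
  scale <- max(stats::mad(resid), eps)
  resid <- pmin(pmax(resid / scale, -clip), clip)
  rk <- rank(-resid, ties.method = "first")
  tibble(gene_id = colnames(m), mean = unname(mu), variance = unname(v),
         residual = unname(resid), rank = unname(rk),
         selected = unname(rk <= n_top))
}

#' Rank spatially variable genes by Moran's I
#'
#' Computes Moran's I ([morans_i()]) of each gene's normalized values on the
#' spot adjacency graph and marks the `n_top` genes with the largest I.
#' A screening substitute for Gaussian-process spatially-variable-gene
#' detection: both rank genes whose expression varies smoothly across the
#' tissue above noise. Genes constant across spots are skipped with a
#' warning (Moran's I is undefined for them).
#'
#' @param ds A [spot_dataset()] with a normalized layer.
#' @param graph A [build_spot_graph()] on the dataset's spots.
#' @param n_top Number of genes to select (0 gives an empty selection).
#' @return Tibble with `gene_id`, `morans_i`, `rank`, `selected` (constant
#'   genes have `NA` I and are never selected).
#' @export
select_svg_morans <- function(ds, graph, n_top) {
  stopifnot(inherits(ds, "spot_dataset"), inherits(graph, "spot_graph"))
  if (n_top > n_genes(ds)) abort("n_top exceeds the number of genes")
  m <- ds$normalized
  if (is.null(m)) abort("normalized layer missing")
  if (!identical(rownames(m), graph$nodes)) {
    m <- m[graph$nodes, , drop = FALSE]
  }
  x <- as.matrix(m)
  const <- apply(x, 2, function(col) max(col) == min(col))
  if (any(const)) {
    warn(paste0(sum(const), " constant gene(s) skipped in Moran's I"))
  }
  I <- rep(NA_real_, ncol(x))
  I[!const] <- morans_i_matrix(x[, !const, drop = FALSE], graph)
  rk <- rank(-I, ties.method = "first", na.last = "keep")
  tibble(gene_id = colnames(x), morans_i = I, rank = rk,
         selected = !is.na(rk) & rk <= n_top)
}
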