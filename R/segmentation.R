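#' Spatially smoothed segmentation by Potts-regularised k-means (ICM)
#'
#' Minimises the Potts objective
#' `E(l) = sum_s ||f_s - mu_l(s)||^2 - beta * sum_(s,t in E) 1[l(s) = l(t)]`
#' by iterated conditional modes: labels are initialised by seeded k-means
#' on the features, then each sweep visits spots in a fixed (row-major)
#' order and reassigns each spot to
#' `argmin_k ||f_s - mu_k||^2 - beta * #neighbours(s) with label k`
#' (current label retained on ties), after which centroids are recomputed.
#' `beta = 0` reduces to plain k-means refinement. Because greedy descent
#' can stall in local minima, `n_starts` seeded k-means initialisations and
#' `n_starts` seeded random initialisations are each descended by ICM and
#' then polished by an exact single-move descent (closed-form energy change
#' of a label move including the centroid update); the labelling with the
#' lowest final energy is returned. Deterministic given `seed`.
#'
#' @param features Numeric matrix, one row per spot, rows aligned with (or
#'   named by) `graph$nodes`; all values finite.
#' @param graph A [build_spot_graph()] on the same spots.
#' @param K Number of clusters (>= 2, <= number of spots).
#' @param beta Spatial smoothness weight (>= 0). Default: a quarter of the
#'   median decision margin (difference of squared distances to the two
#'   nearest initial centroids), which scales the smoothing with the
#'   cluster separation rather than with the noise level.
#' @param max_iter Maximum ICM sweeps per start.
#' @param seed Integer seed (start `i` uses `seed + i - 1`).
#' @param n_starts Number of k-means initialisations.
#' @return An object of class `segmentation_result`: `labels` (tibble
#'   `spot_id`, `cluster` with dense ids `1..K'`), `K`, `centroids`,
#'   `energy`, `n_changed_per_iter`, `params`.
#' @export
segment_spatial <- function(features, graph, K, beta = NULL, max_iter = 100,
                            seed = 1L, n_starts = 5L) {
  stopifnot(inherits(graph, "spot_graph"), K >= 2)
  features <- as.matrix(features)
  if (!all(is.finite(features))) abort("features must be finite")
  n <- nrow(features)
  if (n != length(graph$nodes)) abort("features rows must match graph nodes")
  if (!is.null(rownames(features)) &&
      !identical(rownames(features), graph$nodes)) {
    features <- features[graph$nodes, , drop = FALSE]
  }
  if (K > n) abort("K exceeds the number of spots")

  init_labels <- function(s) {
    withr::with_seed(seed + s - 1L, {
      km <- suppressWarnings(kmeans(features, centers = K, nstart = 5,
                                    iter.max = 50))
      km$cluster
    })
  }
  first_init <- init_labels(1L)
  if (is.null(beta)) {
    # quarter of the median decision margin between the two nearest
    # centroids at init: strong enough to flip isolated discordant spots,
    # but below the between-cluster separation, so smoothing cannot
    # overwhelm the expression signal and collapse the segmentation
    cen <- centroids_of(features, first_init, K)
    d2 <- sq_dist_to_centroids(features, cen)
    two <- t(apply(d2, 1, function(r) sort(r)[1:2]))
    beta <- 0.25 * median(two[, 2] - two[, 1])
  }
  stopifnot(beta >= 0)

  # n_starts k-means initialisations plus n_starts seeded random
  # labelings; each is descended by ICM sweeps and then polished by an
  # exact single-move descent (closed-form energy change including the
  # centroid update), and the lowest-energy labelling wins
  inits <- c(
    lapply(seq_len(n_starts), function(s) {
      if (s == 1L) first_init else init_labels(s)
    }),
    lapply(seq_len(n_starts), function(s) {
      lab <- withr::with_seed(seed + n_starts + s - 1L,
                              sample.int(K, n, replace = TRUE))
      lab[seq_len(min(K, n))] <- seq_len(min(K, n))  # all labels present
      lab
    })
  )
  best <- NULL
  for (lab in inits) {
    fit <- icm_run(features, graph, lab, K, beta, max_iter)
    fit$labels <- repair_empty_clusters(features, fit$labels, K)
    fit$labels <- single_move_descent(features, graph, fit$labels, K, beta)
    fit$energy <- potts_energy(features, graph, fit$labels, beta)
    if (is.null(best) || fit$energy < best$energy) best <- fit
  }

  # dense label ids in order of first appearance
  dense <- match(best$labels, unique(best$labels))
  structure(
    list(labels = tibble(spot_id = graph$nodes, cluster = dense),
         K = length(unique(dense)),
         centroids = centroids_of(features, dense, length(unique(dense))),
         energy = best$energy,
         n_changed_per_iter = best$n_changed,
         params = list(K_requested = K, beta = beta, max_iter = max_iter,
                       seed = seed, n_starts = n_starts,
                       feature_dim = ncol(features),
                       method = "potts_icm")),
    class = "segmentation_result"
  )
}

centroids_of <- function(features, labels, K) {
  cen <- matrix(NA_real_, K, ncol(features))
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    if (length(idx) > 0) {
      cen[k, ] <- colMeans(features[idx, , drop = FALSE])
    }
  }
  cen
}

sq_dist_to_centroids <- function(features, cen) {
  # n x K matrix of squared Euclidean distances (empty clusters -> Inf)
  d2 <- outer(rowSums(features^2), rep(1, nrow(cen))) -
    2 * features %*% Matrix::t(cen) +
    outer(rep(1, nrow(features)), rowSums(cen^2))
  d2 <- as.matrix(d2)
  d2[!is.finite(d2)] <- Inf
  pmax(d2, 0)
}

#' Potts objective of a labelling
#'
#' `sum_s ||f_s - mu_l(s)||^2 - beta * (number of same-label edges)`, with
#' centroids `mu` either supplied or recomputed as label means.
#'
#' @param features Feature matrix (rows aligned with `graph$nodes`).
#' @param graph A [build_spot_graph()].
#' @param labels Integer labels.
#' @param beta Smoothness weight.
#' @param centroids Optional centroid matrix (rows = labels).
#' @return The scalar energy.
#' @export
potts_energy <- function(features, graph, labels, beta, centroids = NULL) {
  K <- max(labels)
  cen <- centroids %||% centroids_of(features, labels, K)
  d2 <- sq_dist_to_centroids(features, cen)
  data_term <- sum(d2[cbind(seq_along(labels), labels)])
  ei <- match(graph$edges$from, graph$nodes)
  ej <- match(graph$edges$to, graph$nodes)
  same <- sum(labels[ei] == labels[ej])
  data_term - beta * same
}

icm_run <- function(features, graph, labels, K, beta, max_iter) {
  n <- nrow(features)
  adj <- graph$adj
  n_changed <- integer(0)
  for (iter in seq_len(max_iter)) {
    cen <- centroids_of(features, labels, K)
    d2 <- sq_dist_to_centroids(features, cen)
    e_before <- sweep_energy(d2, adj, labels, beta)
    changed <- 0L
    for (s in seq_len(n)) {
      nb <- adj[[s]]
      cost <- d2[s, ]
      if (length(nb) > 0) {
        cnt <- tabulate(labels[nb], nbins = K)
        cost <- cost - beta * cnt
      }
      cur <- labels[s]
      best <- which.min(cost)
      if (cost[best] < cost[cur]) {     # retain current label on ties
        labels[s] <- best
        changed <- changed + 1L
      }
    }
    e_after <- sweep_energy(d2, adj, labels, beta)
    if (e_after > e_before + 1e-8) {
      abort("internal error: ICM sweep increased the Potts energy")
    }
    n_changed <- c(n_changed, changed)
    if (changed == 0L) break
  }
  list(labels = labels,
       energy = potts_energy(features, graph, labels, beta),
       n_changed = n_changed)
}

# a K-cluster segmentation partitions the spots into K non-empty
# clusters; ICM sweeps can empty one, in which case the spot farthest
# from its centroid is moved into each empty cluster (deterministic)
repair_empty_clusters <- function(features, labels, K) {
  repeat {
    size <- tabulate(labels, K)
    empty <- which(size == 0)
    if (length(empty) == 0 || sum(size > 1) == 0) break
    cen <- centroids_of(features, labels, K)
    d2own <- rowSums((features - cen[labels, , drop = FALSE])^2)
    movable <- which(size[labels] > 1)
    worst <- movable[which.max(d2own[movable])]
    labels[worst] <- empty[1]
  }
  labels
}

# exact coordinate descent on single-spot moves: the energy change of
# moving spot s from cluster a to b, *including* the centroid update, is
#   n_b/(n_b+1) ||f_s - mu_b||^2 - n_a/(n_a-1) ||f_s - mu_a||^2
#   - beta (neighbours_b - neighbours_a),
# so moves that ICM (which holds centroids fixed within a sweep) cannot
# see are still taken; strictly decreasing, hence terminating
single_move_descent <- function(features, graph, labels, K, beta,
                                max_sweeps = 200) {
  n <- nrow(features)
  adj <- graph$adj
  size <- tabulate(labels, K)
  cen <- centroids_of(features, labels, K)
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (s in seq_len(n)) {
      a <- labels[s]
      if (size[a] <= 1L) next
      fs <- features[s, ]
      d2 <- rowSums(sweep(cen, 2, fs, "-")^2)
      cnt <- tabulate(labels[adj[[s]]], nbins = K)
      occupied <- which(size > 0 & seq_len(K) != a)
      if (length(occupied) == 0) next
      delta <- size[occupied] / (size[occupied] + 1) * d2[occupied] -
        size[a] / (size[a] - 1) * d2[a] -
        beta * (cnt[occupied] - cnt[a])
      j <- which.min(delta)
      if (delta[j] < -1e-12) {
        b <- occupied[j]
        cen[a, ] <- (cen[a, ] * size[a] - fs) / (size[a] - 1)
        cen[b, ] <- (cen[b, ] * size[b] + fs) / (size[b] + 1)
        size[a] <- size[a] - 1L
        size[b] <- size[b] + 1L
        labels[s] <- b
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  labels
}

# energy at fixed distance matrix (fixed centroids)
sweep_energy <- function(d2, adj, labels, beta) {
  same <- 0L
  for (s in seq_along(adj)) {
    same <- same + sum(labels[adj[[s]]] == labels[s])
  }
  sum(d2[cbind(seq_along(labels), labels)]) - beta * same / 2
}

#' Non-spatial graph-community clustering of spots
#'
#' The control clustering: features are reduced to `n_pcs` principal
#' components (SVD of the centered matrix), a k-nearest-neighbour graph is
#' built in PC space, and modularity-based Leiden community detection is run
#' at the given resolution. With `K_target` set, the resolution is searched
#' (geometric grid, then refinement) for a partition with exactly that many
#' communities; if none is found, the finest partition with at least
#' `K_target` communities is merged down by hierarchical clustering of
#' community centroids.
#'
#' @param features Numeric matrix, one row per spot (rownames used as spot
#'   ids when present).
#' @param k_neighbors Neighbours in the kNN graph (default 15).
#' @param resolution Leiden modularity resolution (ignored when `K_target`
#'   is set). The default 0.1 is chosen so that clearly separated point
#'   clouds come out as single communities on sparse kNN graphs; raise it
#'   to resolve finer structure.
#' @param seed Integer seed.
#' @param n_pcs Number of principal components (capped at the matrix rank).
#' @param K_target Optional exact number of clusters to obtain.
#' @return A `segmentation_result` (method `"leiden"`).
#' @export
cluster_expression <- function(features, k_neighbors = 15, resolution = 0.1,
                               seed = 1L, n_pcs = 20, K_target = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  ids <- rownames(features) %||% sprintf("spot_%05d", seq_len(n))
  n_pcs <- min(n_pcs, n - 1, ncol(features))
  if (n_pcs < 1) abort("not enough dimensions for PCA")
  pcs <- prcomp(features, center = TRUE, scale. = FALSE,
                rank. = n_pcs)$x
  k_neighbors <- min(k_neighbors, n - 1)
  d <- as.matrix(dist(pcs))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  edges <- unique(t(apply(
    cbind(rep(seq_len(n), k_neighbors), as.vector(nn)), 1, sort
  )))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)

  run_leiden <- function(res) {
    withr::with_seed(seed, igraph::cluster_leiden(
      g, objective_function = "modularity", resolution = res,
      n_iterations = 5
    ))$membership
  }

  if (is.null(K_target)) {
    mem <- run_leiden(resolution)
  } else {
    stopifnot(K_target >= 1)
    mem <- NULL
    grid <- 10^seq(-4, 1.5, length.out = 40)
    for (res in grid) {
      cand <- run_leiden(res)
      if (length(unique(cand)) == K_target) {
        mem <- cand
        break
      }
      if (length(unique(cand)) > K_target) {
        # merge excess communities via their centroids
        cen <- centroids_of(pcs, match(cand, unique(cand)),
                            length(unique(cand)))
        hc <- stats::hclust(dist(cen), method = "ward.D2")
        merged <- stats::cutree(hc, k = K_target)
        mem <- merged[match(cand, unique(cand))]
        break
      }
    }
    if (is.null(mem)) {
      abort("could not reach K_target communities at any resolution")
    }
  }
  dense <- match(mem, unique(mem))
  structure(
    list(labels = tibble(spot_id = ids, cluster = dense),
         K = length(unique(dense)),
         centroids = centroids_of(pcs, dense, length(unique(dense))),
         energy = NA_real_, n_changed_per_iter = integer(),
         params = list(k_neighbors = k_neighbors, resolution = resolution,
                       seed = seed, n_pcs = n_pcs, K_target = K_target,
                       method = "leiden")),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("<segmentation_result> ", nrow(x$labels), " spots, K = ", x$K,
      " (", x$params$method, ")\n", sep = "")
  invisible(x)
}
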