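# Independent oracles used by the equivalence tests. Deliberately naive
# implementations, kept free of any package internals.

# breadth-first-search connected components on an edge list
bfs_components <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    comp <- character()
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      for (w in adj[[u]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

bfs_largest_component <- function(nodes, edges) {
  comps <- bfs_components(nodes, edges)
  sizes <- lengths(comps)
  best <- comps[sizes == max(sizes)]
  mins <- vapply(best, min, character(1))
  best[[order(mins)[1]]]
}

# exact two-sided/one-sided Mann-Whitney p by enumeration of all
# choose(nx+ny, nx) group assignments of the pooled sample (no ties)
enumerate_mw_p <- function(x, y, alternative = "two_sided") {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  switch(alternative,
         greater = mean(us >= u_obs),
         less = mean(us <= u_obs),
         two_sided = min(1, 2 * min(mean(us >= u_obs), mean(us <= u_obs))))
}

# hypergeometric upper tail by direct pmf summation with lchoose
hyper_upper_tail <- function(q, total_hits, universe, draws) {
  ks <- q:min(draws, total_hits)
  if (q == 0) return(1)
  sum(exp(lchoose(total_hits, ks) +
            lchoose(universe - total_hits, draws - ks) -
            lchoose(universe, draws)))
}

# textbook step-up BH
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force minimum of the Potts objective over all two-cluster
# labelings (both clusters non-empty: the K = 2 segmentation space)
brute_force_potts <- function(features, graph, beta) {
  n <- nrow(features)
  stopifnot(n <= 14)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code)[1:n]) + 1L
    e <- potts_energy(features, graph, lab, beta)
    if (e < best) best <- e
  }
  best
}

# convex hull area oracle via grDevices::chull
convex_hull_area <- function(pts) {
  h <- grDevices::chull(pts)
  ring <- pts[c(h, h[1]), ]
  abs(sum(ring[-nrow(ring), 1] * ring[-1, 2] -
            ring[-1, 1] * ring[-nrow(ring), 2])) / 2
}

# small preprocessed two-clone sample for mapping tests
small_mapped_sample <- function(seed = 1, n = 12, genes = 300,
                                informative = 60, contamination = 0.2) {
  p <- sim_params(n_rows = n, n_cols = n, n_genes = genes,
                  contamination = contamination, seed = seed)
  truth <- make_synthetic_truth(p, n_informative = informative)
  ds <- simulate_counts(truth)
  ds <- filter_spots(ds, min_counts = 10, min_genes = 5)
  ds <- filter_genes(ds, min_spots = 2)
  ds <- normalize_log1p(ds)
  list(params = p, truth = truth, ds = ds,
       graph = build_spot_graph(ds),
       true_clone = setNames(truth$clone_field$clone,
                             truth$clone_field$spot_id))
}
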