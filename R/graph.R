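#' Build a spot adjacency graph from positions
#'
#' Spots are connected iff their centers are within `max_dist_um`
#' (inclusive). The default `max_dist_um` is 1.2 times the minimum nonzero
#' center spacing, which on a hexagonal lattice captures exactly the six
#' first-ring neighbours and excludes the second ring.
#'
#' @param positions A [spot_dataset()] or a data frame with columns
#'   `barcode`, `x_um`, `y_um` (one row per spot).
#' @param max_dist_um Neighbour distance threshold in micrometres.
#' @return An object of class `spot_graph`: `nodes` (barcodes), `edges`
#'   (tibble `from`, `to` as barcodes, each unordered pair once), `adj`
#'   (per-node integer adjacency list), `max_dist_um`, `coords`.
#' @export
build_spot_graph <- function(positions, max_dist_um = NULL) {
  if (inherits(positions, "spot_dataset")) positions <- spot_positions(positions)
  stopifnot(all(c("barcode", "x_um", "y_um") %in% names(positions)))
  n <- nrow(positions)
  if (n < 2) abort("need at least 2 spots to build a graph")
  coords <- cbind(positions$x_um, positions$y_um)
  d <- as.matrix(dist(coords))
  if (is.null(max_dist_um)) {
    nz <- d[d > 0]
    if (length(nz) == 0) abort("all spots are at the same position")
    max_dist_um <- 1.2 * min(nz)
  }
  keep <- which(d <= max_dist_um & upper.tri(d), arr.ind = TRUE)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(keep) > 0) {
    adj_from <- split(keep[, 2], keep[, 1])
    adj_to <- split(keep[, 1], keep[, 2])
    for (k in names(adj_from)) {
      i <- as.integer(k)
      adj[[i]] <- c(adj[[i]], as.integer(adj_from[[k]]))
    }
    for (k in names(adj_to)) {
      i <- as.integer(k)
      adj[[i]] <- c(adj[[i]], as.integer(adj_to[[k]]))
    }
    adj <- lapply(adj, sort)
  }
  structure(
    list(nodes = positions$barcode,
         edges = tibble(from = positions$barcode[keep[, 1]],
                        to = positions$barcode[keep[, 2]]),
         adj = adj, max_dist_um = max_dist_um,
         coords = stats::setNames(as.data.frame(coords), c("x_um", "y_um"))),
    class = "spot_graph"
  )
}

#' @export
print.spot_graph <- function(x, ...) {
  cat("<spot_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (max_dist ", signif(x$max_dist_um, 4), " um)\n", sep = "")
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges, directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
}

# sparse row-normalized weight matrix of a spot_graph
row_normalized_weights <- function(graph) {
  n <- length(graph$nodes)
  deg <- lengths(graph$adj)
  i <- rep(seq_len(n), deg)
  j <- unlist(graph$adj)
  if (length(j) == 0) abort("graph has no edges")
  sparseMatrix(i = i, j = j, x = 1 / deg[i], dims = c(n, n))
}

#' Largest connected component of an induced subgraph
#'
#' Restricts the graph to `spot_subset` and returns the connected component
#' with the most spots. Ties are broken deterministically in favour of the
#' component containing the lexicographically smallest spot id.
#'
#' @param spot_subset Character vector of spot ids (subset of graph nodes).
#' @param graph A [build_spot_graph()] object.
#' @return Character vector of the component's spot ids (sorted).
#' @export
largest_connected_component <- function(spot_subset, graph) {
  stopifnot(inherits(graph, "spot_graph"))
  if (length(spot_subset) == 0) abort("empty spot subset")
  if (!all(spot_subset %in% graph$nodes)) {
    abort("spot_subset contains ids not in the graph")
  }
  g <- igraph::induced_subgraph(as_igraph(graph),
                                vids = unique(spot_subset))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mins <- vapply(best, function(k) {
      min(igraph::V(g)$name[comp$membership == k])
    }, character(1))
    best <- best[order(mins)][1]
  }
  sort(igraph::V(g)$name[comp$membership == best])
}
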