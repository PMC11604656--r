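#' Concave hull (alpha shape) of a point set
#'
#' Computes the alpha shape: the Delaunay triangulation (via
#' \pkg{deldir}) restricted to triangles with circumradius `<= 1 / alpha`,
#' whose union is the shape; the returned boundary consists of the edges
#' belonging to exactly one kept triangle, assembled into closed rings
#' (outer boundaries and hole boundaries). As `alpha -> 0` every triangle is
#' kept and the convex hull is recovered.
#'
#' @param points Two-column matrix or data frame of x/y coordinates (um),
#'   at least 3 non-collinear points.
#' @param alpha Shape parameter (1/alpha is the circumradius cutoff);
#'   default `1 / (1.5 * d_min)` with `d_min` the minimum nonzero point
#'   spacing, which keeps triangles between lattice neighbours and removes
#'   triangles spanning holes.
#' @return An object of class `concave_hull`: `rings` (list of closed
#'   coordinate matrices), `area` (sum of kept triangle areas, um^2),
#'   `alpha`, `n_triangles_kept`.
#' @export
concave_hull <- function(points, alpha = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  colnames(pts) <- c("x", "y")
  if (nrow(pts) < 3) abort("need at least 3 points")
  if (is.null(alpha)) {
    d <- dist(pts)
    dmin <- min(d[d > 0])
    alpha <- 1 / (1.5 * dmin)
  }
  stopifnot(alpha > 0)
  tri <- tryCatch(
    deldir::triang.list(deldir::deldir(pts[, 1], pts[, 2],
                                       suppressMsge = TRUE)),
    error = function(e) list()
  )
  if (length(tri) == 0) abort("no triangulation: points may be collinear")

  circumradius <- function(t) {
    a <- sqrt((t$x[1] - t$x[2])^2 + (t$y[1] - t$y[2])^2)
    b <- sqrt((t$x[2] - t$x[3])^2 + (t$y[2] - t$y[3])^2)
    cc <- sqrt((t$x[3] - t$x[1])^2 + (t$y[3] - t$y[1])^2)
    s <- (a + b + cc) / 2
    area <- sqrt(max(s * (s - a) * (s - b) * (s - cc), 0))
    if (area == 0) return(Inf)
    a * b * cc / (4 * area)
  }
  tri_area <- function(t) {
    abs((t$x[2] - t$x[1]) * (t$y[3] - t$y[1]) -
          (t$x[3] - t$x[1]) * (t$y[2] - t$y[1])) / 2
  }
  keep <- vapply(tri, function(t) circumradius(t) <= 1 / alpha, logical(1))
  if (!any(keep)) {
    abort("alpha too large: no triangle has circumradius <= 1/alpha")
  }
  kept <- tri[keep]

  # boundary = edges used by exactly one kept triangle
  edges <- do.call(rbind, lapply(kept, function(t) {
    v <- t$ptNum
    rbind(sort(v[1:2]), sort(v[2:3]), sort(v[c(1, 3)]))
  }))
  key <- paste(edges[, 1], edges[, 2])
  boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]

  rings <- assemble_rings(boundary, pts)
  structure(
    list(rings = rings,
         area = sum(vapply(kept, tri_area, numeric(1))),
         alpha = alpha, n_triangles_kept = length(kept)),
    class = "concave_hull"
  )
}

# walk boundary edges into closed rings; vertices with degree > 2 (pinch
# points) are handled by consuming edges greedily
assemble_rings <- function(boundary, pts) {
  if (nrow(boundary) == 0) return(list())
  used <- rep(FALSE, nrow(boundary))
  inc <- split(rep(seq_len(nrow(boundary)), 2),
               factor(c(boundary[, 1], boundary[, 2])))
  inc_of <- function(v) inc[[as.character(v)]]
  rings <- list()
  repeat {
    start_e <- which(!used)[1]
    if (is.na(start_e)) break
    used[start_e] <- TRUE
    start_v <- boundary[start_e, 1]
    cur_v <- boundary[start_e, 2]
    ring <- c(start_v, cur_v)
    while (cur_v != start_v) {
      nxt <- setdiff(inc_of(cur_v)[!used[inc_of(cur_v)]], integer(0))
      if (length(nxt) == 0) break
      e <- nxt[1]
      used[e] <- TRUE
      cur_v <- setdiff(boundary[e, ], cur_v)[1]
      ring <- c(ring, cur_v)
    }
    rings[[length(rings) + 1]] <- pts[ring, , drop = FALSE]
  }
  rings
}

#' @export
print.concave_hull <- function(x, ...) {
  cat("<concave_hull> area ", signif(x$area, 6), " um^2, ",
      length(x$rings), " boundary ring(s), alpha = ", signif(x$alpha, 4),
      "\n", sep = "")
  invisible(x)
}

#' Point-in-hull test (boundary inclusive)
#'
#' Even-odd rule over the hull's boundary rings (so holes are excluded and
#' disconnected pieces included); points on a boundary edge or vertex count
#' as inside.
#'
#' @param hull A [concave_hull()].
#' @param x,y Coordinate vectors.
#' @return Logical vector.
#' @export
point_in_hull <- function(hull, x, y) {
  stopifnot(inherits(hull, "concave_hull"))
  inside_count <- integer(length(x))
  on_boundary <- logical(length(x))
  for (ring in hull$rings) {
    code <- sp::point.in.polygon(x, y, ring[, 1], ring[, 2])
    inside_count <- inside_count + (code == 1)
    on_boundary <- on_boundary | code >= 2
  }
  on_boundary | (inside_count %% 2 == 1)
}

#' Clone territories from a clone map
#'
#' For each clone, takes the largest connected component of its spots in
#' the adjacency graph (discarding stray mislabelled spots) and outlines it
#' with the concave hull of the component's spot centers.
#'
#' @param clone_map A [map_clones()] result (or a tibble with `spot_id`,
#'   `clone`).
#' @param graph The [build_spot_graph()] used for mapping.
#' @param alpha Alpha-shape parameter; default `1 / (1.5 * spacing)` with
#'   the spacing inferred from the graph (`max_dist_um / 1.2`).
#' @return List of class `clone_territories`; each element has `clone`,
#'   `spots`, `hull`, `alpha`.
#' @export
clone_territories <- function(clone_map, graph, alpha = NULL) {
  assignments <- if (inherits(clone_map, "clone_map")) {
    clone_map$assignments
  } else {
    clone_map
  }
  stopifnot(all(c("spot_id", "clone") %in% names(assignments)),
            inherits(graph, "spot_graph"))
  alpha <- alpha %||% (1 / (1.5 * graph$max_dist_um / 1.2))
  coords <- graph$coords
  terr <- lapply(sort(unique(assignments$clone)), function(cl) {
    spots <- assignments$spot_id[assignments$clone == cl]
    lcc <- largest_connected_component(spots, graph)
    idx <- match(lcc, graph$nodes)
    hull <- concave_hull(cbind(coords$x_um[idx], coords$y_um[idx]),
                         alpha = alpha)
    list(clone = cl, spots = lcc, hull = hull, alpha = alpha)
  })
  names(terr) <- vapply(terr, `[[`, character(1), "clone")
  structure(terr, class = "clone_territories")
}

#' Assign nuclei to clone territories by centroid location
#'
#' A nucleus is assigned to the clone whose territory hull contains its
#' centroid (boundary inclusive). Nuclei inside several territories are set
#' to `"unassigned"` with a warning; nuclei outside all territories are
#' `"unassigned"`.
#'
#' @param nuclei Nucleus tibble (`nucleus_id`, `x_um`, `y_um`, `area_um2`,
#'   extra columns preserved).
#' @param territories A [clone_territories()] object.
#' @return The nucleus tibble with a `clone` column.
#' @export
assign_nuclei <- function(nuclei, territories) {
  stopifnot(inherits(territories, "clone_territories"))
  inside <- vapply(territories, function(t) {
    point_in_hull(t$hull, nuclei$x_um, nuclei$y_um)
  }, logical(nrow(nuclei)))
  inside <- matrix(inside, nrow = nrow(nuclei),
                   dimnames = list(NULL, names(territories)))
  n_in <- rowSums(inside)
  clone <- rep("unassigned", nrow(nuclei))
  one <- n_in == 1
  clone[one] <- colnames(inside)[max.col(inside[one, , drop = FALSE])]
  if (any(n_in > 1)) {
    warn(paste0(sum(n_in > 1),
                " nuclei fall inside multiple territories; unassigned"))
  }
  dplyr::mutate(nuclei, clone = clone)
}

#' Compare nuclear areas between clones
#'
#' Two-sided Mann-Whitney test of nucleus area between clone-A and clone-B
#' assigned nuclei, with per-clone medians.
#'
#' @param nuclei Nucleus tibble with `clone` and `area_um2` columns.
#' @param clones The two clone labels to compare.
#' @return Tibble with `median_A`, `median_B`, `median_ratio`, `U`,
#'   `p_two_sided`, `n_A`, `n_B`.
#' @export
compare_nuclear_area <- function(nuclei, clones = c("A", "B")) {
  a <- nuclei$area_um2[nuclei$clone == clones[1]]
  b <- nuclei$area_um2[nuclei$clone == clones[2]]
  if (length(a) == 0 || length(b) == 0) {
    abort("a clone has no assigned nuclei")
  }
  mw <- mann_whitney_u(a, b, "two_sided")
  tibble(median_A = median(a), median_B = median(b),
         median_ratio = median(a) / median(b),
         U = mw$U, p_two_sided = mw$p,
         n_A = length(a), n_B = length(b))
}
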