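test_that("largest connected component matches hand cases and the BFS oracle", {
  pos <- tibble::tibble(barcode = as.character(1:5),
                        x_um = c(0, 100, 200, 1000, 1100), y_um = 0)
  g <- build_spot_graph(pos, max_dist_um = 100)  # edges 1-2, 2-3, 4-5
  expect_equal(largest_connected_component(as.character(1:5), g),
               c("1", "2", "3"))
  expect_setequal(largest_connected_component(c("4", "5"), g), c("4", "5"))
  expect_error(largest_connected_component(character(), g), "empty")
  expect_error(largest_connected_component("zz", g), "not in the graph")

  # random geometric graphs vs BFS
  for (trial in 1:30) {
    withr::with_seed(trial, {
      n <- sample(5:50, 1)
      pos <- tibble::tibble(barcode = sprintf("n%02d", 1:n),
                            x_um = runif(n, 0, 400),
                            y_um = runif(n, 0, 400))
      subset <- sample(pos$barcode, sample(2:n, 1))
    })
    g <- build_spot_graph(pos, max_dist_um = 120)
    edges <- as.matrix(g$edges)
    sub_edges <- edges[edges[, 1] %in% subset & edges[, 2] %in% subset, ,
                       drop = FALSE]
    expect_identical(largest_connected_component(subset, g),
                     bfs_largest_component(sort(subset), sub_edges))
  }
})

test_that("alpha shape recovers the convex hull in the small-alpha limit", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  h <- concave_hull(sq, alpha = 1e-9)
  expect_equal(h$area, 1, tolerance = 1e-9)
  expect_equal(length(h$rings), 1)

  withr::with_seed(1, pts <- cbind(runif(40), runif(40)))
  h2 <- concave_hull(pts, alpha = 1e-9)
  expect_equal(h2$area, convex_hull_area(pts), tolerance = 1e-6)
})

test_that("a suitable alpha carves concavities out of an L-shaped cloud", {
  # L-shape on a unit grid
  g <- expand.grid(x = 0:10, y = 0:10)
  keep <- g$x <= 3 | g$y <= 3
  pts <- as.matrix(g[keep, ])
  h <- concave_hull(pts, alpha = 1 / 1.5)
  expect_lt(h$area, convex_hull_area(pts) - 1)
  # all input points inside or on the hull
  expect_true(all(point_in_hull(h, pts[, 1], pts[, 2])))
  # a point in the carved-out corner is outside
  expect_false(point_in_hull(h, 8, 8))

  expect_error(concave_hull(pts, alpha = 100), "alpha too large")
  expect_error(concave_hull(cbind(0:5, 0:5)), "collinear")
  expect_error(concave_hull(sq <- cbind(0:1, 0:1)), "at least 3")
})

test_that("territories contain their spots and assignment is translation invariant", {
  s <- small_mapped_sample(seed = 51)
  cm <- map_clones(s$ds, s$truth$annotation, s$truth$cnv_profiles, s$graph,
                   seed = 1)
  terr <- clone_territories(cm, s$graph)
  for (t in terr) {
    idx <- match(t$spots, s$graph$nodes)
    expect_true(all(point_in_hull(t$hull, s$graph$coords$x_um[idx],
                                  s$graph$coords$y_um[idx])))
  }

  nuc <- simulate_nuclei(s$truth$clone_field, 1200, seed = 2)
  asg <- assign_nuclei(nuc, terr)
  assigned <- asg$clone != "unassigned"
  expect_gt(mean(assigned), 0.7)
  expect_gte(mean(asg$clone[assigned] == asg$true_clone[assigned]), 0.9)

  # translating everything leaves assignments unchanged
  g2 <- s$graph
  g2$coords$x_um <- g2$coords$x_um + 5000
  g2$coords$y_um <- g2$coords$y_um - 3000
  terr2 <- clone_territories(cm, g2)
  nuc2 <- dplyr::mutate(nuc, x_um = x_um + 5000, y_um = y_um - 3000)
  asg2 <- assign_nuclei(nuc2, terr2)
  expect_identical(asg$clone, asg2$clone)
})

test_that("nucleus assignment handles boundary, outside and overlap cases", {
  tri1 <- concave_hull(cbind(c(0, 2, 2, 0), c(0, 0, 2, 2)), alpha = 1e-9)
  tri2 <- concave_hull(cbind(c(1.5, 3.5, 3.5, 1.5), c(0, 0, 2, 2)),
                       alpha = 1e-9)
  terr <- structure(list(A = list(clone = "A", spots = character(),
                                  hull = tri1, alpha = 1e-9),
                         B = list(clone = "B", spots = character(),
                                  hull = tri2, alpha = 1e-9)),
                    class = "clone_territories")
  nuc <- tibble::tibble(nucleus_id = c("in_A", "on_A_edge", "overlap",
                                       "outside"),
                        x_um = c(0.5, 0, 1.8, 10), y_um = c(0.5, 1, 1, 10),
                        area_um2 = 30)
  expect_warning(asg <- assign_nuclei(nuc, terr), "multiple")
  expect_equal(asg$clone, c("A", "A", "unassigned", "unassigned"))
})

test_that("nuclear area comparison matches exact enumeration on small samples", {
  nuc <- tibble::tibble(nucleus_id = as.character(1:7),
                        clone = c(rep("A", 4), rep("B", 3)),
                        area_um2 = c(50, 60, 70, 80, 10, 20, 30))
  r <- compare_nuclear_area(nuc)
  expect_equal(r$median_A, 65)
  expect_equal(r$median_B, 20)
  expect_equal(r$p_two_sided,
               enumerate_mw_p(c(50, 60, 70, 80), c(10, 20, 30),
                              "two_sided"),
               tolerance = 1e-12)
  expect_error(compare_nuclear_area(dplyr::filter(nuc, clone == "A")),
               "no assigned nuclei")
})
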