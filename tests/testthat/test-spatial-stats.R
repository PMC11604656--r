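test_that("heterogeneity index counts only clusters above the size floor", {
  labels <- rep(1:4, times = c(50, 40, 6, 4))
  h <- heterogeneity_index(labels, n_spots = 100)
  expect_equal(h$n_clusters_kept, 3)
  expect_equal(h$index, 0.03)
  # single cluster
  expect_equal(heterogeneity_index(rep(1, 20))$index, 1 / 20)
  # invariant to relabeling
  relab <- c(9, 2, 7, 5)[labels]
  expect_equal(heterogeneity_index(relab, n_spots = 100)$index, 0.03)
  expect_error(heterogeneity_index(labels, n_spots = 0), "positive")
})

test_that("spatial variance fraction is a region R-squared", {
  expect_equal(spatial_variance_fraction(c(0, 0, 1, 1), c(1, 1, 2, 2)), 1)
  # affine invariance
  withr::with_seed(1, v <- rnorm(60))
  lab <- rep(1:3, 20)
  f1 <- spatial_variance_fraction(v, lab)
  f2 <- spatial_variance_fraction(3 * v - 7, lab)
  expect_equal(f1, f2)
  expect_gte(f1, 0); expect_lte(f1, 1)
  # region-independent values: ~ 0 for large n (permutation expectation)
  withr::with_seed(2, {
    fracs <- replicate(50, spatial_variance_fraction(rnorm(500),
                                                     rep(1:5, 100)))
  })
  expect_lt(mean(fracs), 0.03)
  expect_error(spatial_variance_fraction(rep(1, 4), c(1, 1, 2, 2)),
               "constant")
})

test_that("Moran's I matches closed forms and the permutation null", {
  pos2 <- tibble::tibble(barcode = c("a", "b"), x_um = c(0, 100), y_um = 0)
  g2 <- build_spot_graph(pos2)
  expect_equal(morans_i(c(1, -1), g2), -1)

  # smooth gradient on a path graph: positive autocorrelation
  posn <- tibble::tibble(barcode = sprintf("s%02d", 1:20),
                         x_um = (1:20) * 100, y_um = 0)
  gn <- build_spot_graph(posn)
  expect_gt(morans_i(1:20, gn), 0)

  # permutation-null mean ~ -1/(n-1)
  withr::with_seed(3, {
    v <- rnorm(20)
    Is <- replicate(3000, morans_i(sample(v), gn))
  })
  expect_equal(mean(Is), -1 / 19, tolerance = 0.02)
  expect_error(morans_i(rep(1, 20), gn), "constant")
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  withr::with_seed(4, {
    pos <- tibble::tibble(barcode = sprintf("s%02d", 1:30),
                          x_um = runif(30, 0, 500),
                          y_um = runif(30, 0, 500))
    v <- rnorm(30)
  })
  g <- build_spot_graph(pos, max_dist_um = 200)
  w <- matrix(0, 30, 30)
  for (i in seq_len(30)) w[i, g$adj[[i]]] <- 1 / length(g$adj[[i]])
  expect_equal(morans_i(v, g),
               ape::Moran.I(v, w, scaled = FALSE)$observed,
               tolerance = 1e-10)
})

test_that("Mann-Whitney switches between exact enumeration and the approximation", {
  r <- mann_whitney_u(c(1, 2), c(3, 4), "two_sided")
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  # all inputs with nx + ny <= 10 match full enumeration
  withr::with_seed(5, {
    for (nx in 1:5) {
      for (ny in 1:5) {
        x <- rnorm(nx); y <- rnorm(ny)
        for (alt in c("two_sided", "less", "greater")) {
          expect_equal(mann_whitney_u(x, y, alt)$p,
                       enumerate_mw_p(x, y, alt), tolerance = 1e-12)
        }
      }
    }
  })

  # fully tied degenerate case
  expect_equal(mann_whitney_u(1, 1, "two_sided")$p, 1)

  # approximation close to exact at n = 8 + 8
  withr::with_seed(6, {
    x <- rnorm(8); y <- rnorm(8, 0.5)
  })
  p_exact <- mann_whitney_u(x, y, "two_sided")$p
  p_approx <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  )
  expect_lt(abs(p_exact - p_approx), 0.01)

  # two-sided p symmetric in the sample order
  expect_equal(mann_whitney_u(x, y, "two_sided")$p,
               mann_whitney_u(y, x, "two_sided")$p)
  expect_error(mann_whitney_u(numeric(0), y), "empty")
})

test_that("hypergeometric enrichment equals brute-force combinatorics", {
  expect_equal(hypergeometric_enrichment(0, 5, 5, 10), 1)
  # draw 4 of 10, 5 marked, all 4 hits: C(5,4)/C(10,4) = 5/210
  expect_equal(hypergeometric_enrichment(4, 4, 5, 10), 5 / 210,
               tolerance = 1e-12)
  # random tables match pmf summation to 1e-12 relative
  withr::with_seed(7, {
    for (i in 1:50) {
      universe <- sample(5:30, 1)
      hits_total <- sample(0:universe, 1)
      set_size <- sample(1:universe, 1)
      obs <- sample(0:min(set_size, hits_total), 1)
      expect_equal(hypergeometric_enrichment(obs, set_size, hits_total,
                                             universe),
                   hyper_upper_tail(obs, hits_total, universe, set_size),
                   tolerance = 1e-12)
    }
  })
  # log-space survives tiny tails
  lp <- hypergeometric_enrichment(400, 500, 450, 5000, log.p = TRUE)
  expect_true(is.finite(lp) && lp < -100)
  expect_error(hypergeometric_enrichment(6, 5, 5, 10), "inconsistent")
})

test_that("BH adjustment matches the textbook step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(8, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_stepup(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-15))
      # monotone: ordering of q follows ordering of p
      expect_true(all(diff(q[order(p)]) >= -1e-15))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})
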