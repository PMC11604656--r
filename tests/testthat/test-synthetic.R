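test_that("half_split clone fields split the lattice by column and are connected", {
  p <- sim_params(n_rows = 4, n_cols = 4, n_genes = 10, seed = 1)
  field <- generate_clone_field(p)
  expect_equal(sum(field$clone == "A"), 8)
  expect_equal(sum(field$clone == "B"), 8)
  expect_true(all(field$clone[field$array_col < 2] == "A"))
  # each clone connected under hex adjacency
  g <- build_spot_graph(
    tibble::tibble(barcode = field$spot_id, x_um = field$x_um,
                   y_um = field$y_um)
  )
  for (cl in c("A", "B")) {
    spots <- field$spot_id[field$clone == cl]
    expect_setequal(largest_connected_component(spots, g), spots)
  }
})

test_that("blob clone fields are deterministic and spatially coherent", {
  p <- sim_params(n_rows = 12, n_cols = 12, n_genes = 10, layout = "blob",
                  seed = 42)
  f1 <- generate_clone_field(p)
  f2 <- generate_clone_field(p)
  expect_identical(f1$clone, f2$clone)

  # adjacent spots mostly share a label when smoothing is wide
  frac <- vapply(1:20, function(s) {
    pp <- sim_params(n_rows = 40, n_cols = 40, n_genes = 10,
                     layout = "blob", blob_smooth_um = 300, seed = s)
    f <- generate_clone_field(pp)
    g <- build_spot_graph(
      tibble::tibble(barcode = f$spot_id, x_um = f$x_um, y_um = f$y_um)
    )
    lab <- setNames(f$clone, f$spot_id)
    mean(lab[g$edges$from] == lab[g$edges$to])
  }, numeric(1))
  expect_gt(mean(frac), 0.9)
})

test_that("count simulation follows the dosage-contamination mean model", {
  # c = 0: empirical clone mean ratio of informative genes ~ dosage 2
  p <- sim_params(n_rows = 40, n_cols = 40, n_genes = 200,
                  contamination = 0, libsize_sd = 0, seed = 11)
  tr <- make_synthetic_truth(p, n_informative = 80)
  ds <- simulate_counts(tr)
  a_spots <- tr$clone_field$spot_id[tr$clone_field$clone == "A"]
  b_spots <- tr$clone_field$spot_id[tr$clone_field$clone == "B"]
  mean_a <- mean(as.matrix(ds$counts[a_spots, tr$informative_genes]))
  mean_b <- mean(as.matrix(ds$counts[b_spots, tr$informative_genes]))
  expect_equal(mean_a / mean_b, 2, tolerance = 0.1)

  # c = 1 cancels the dosage
  p1 <- sim_params(n_rows = 20, n_cols = 20, n_genes = 200,
                   contamination = 1, libsize_sd = 0, seed = 12)
  tr1 <- make_synthetic_truth(p1, n_informative = 80)
  ds1 <- simulate_counts(tr1)
  a1 <- tr1$clone_field$spot_id[tr1$clone_field$clone == "A"]
  b1 <- tr1$clone_field$spot_id[tr1$clone_field$clone == "B"]
  r1 <- mean(as.matrix(ds1$counts[a1, tr1$informative_genes])) /
    mean(as.matrix(ds1$counts[b1, tr1$informative_genes]))
  expect_equal(r1, 1, tolerance = 0.1)

  # large theta: Poisson limit, variance ~ mean per gene
  p2 <- sim_params(n_rows = 30, n_cols = 30, n_genes = 50,
                   contamination = 0, libsize_sd = 0, gene_logmean_sd = 0,
                   baseline_mean = 5, nb_dispersion = 1e7, seed = 13)
  tr2 <- make_synthetic_truth(p2, n_informative = 2)
  ds2 <- simulate_counts(tr2)
  neutral <- setdiff(colnames(ds2$counts), tr2$informative_genes)
  x <- as.matrix(ds2$counts[, neutral])
  ratio <- apply(x, 2, var) / colMeans(x)
  expect_equal(mean(ratio), 1, tolerance = 0.1)

  # bit-reproducible given the same params
  expect_identical(as.matrix(simulate_counts(tr2)$counts),
                   as.matrix(ds2$counts))
})

test_that("informative-gene contrast follows the closed-form mixture mean", {
  # expected ratio: ((1-c) d + c) / ((1-c) + c) with B diploid, d = 2
  c <- 0.4
  p <- sim_params(n_rows = 40, n_cols = 40, n_genes = 200,
                  contamination = c, libsize_sd = 0, seed = 21)
  tr <- make_synthetic_truth(p, n_informative = 100)
  ds <- simulate_counts(tr)
  a <- tr$clone_field$spot_id[tr$clone_field$clone == "A"]
  b <- tr$clone_field$spot_id[tr$clone_field$clone == "B"]
  obs <- mean(as.matrix(ds$counts[a, tr$informative_genes])) /
    mean(as.matrix(ds$counts[b, tr$informative_genes]))
  expect_equal(obs, (1 - c) * 2 + c, tolerance = 0.08)
})

test_that("nucleus simulation matches its clone-wise area parameterisation", {
  p <- sim_params(n_rows = 14, n_cols = 14, n_genes = 10, seed = 5)
  field <- generate_clone_field(p)
  nuc <- simulate_nuclei(field, density_per_mm2 = 1800, seed = 7)
  expect_gt(nrow(nuc), 2000)
  med <- tapply(nuc$area_um2, nuc$true_clone, median)
  expect_equal(unname(med["A"] / med["B"]), 1.5, tolerance = 0.1)

  # equal parameters: Mann-Whitney p uniform over repeated simulations
  small <- sim_params(n_rows = 5, n_cols = 5, n_genes = 10, seed = 6)
  sf <- generate_clone_field(small)
  pvals <- vapply(1:200, function(s) {
    nn <- simulate_nuclei(sf, 2500,
                          area_meanlog = c(A = log(35), B = log(35)),
                          seed = s)
    mann_whitney_u(nn$area_um2[nn$true_clone == "A"],
                   nn$area_um2[nn$true_clone == "B"], "two_sided")$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)

  # vanishing density: empty table, no error
  empty <- simulate_nuclei(field, density_per_mm2 = 1e-9, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(simulate_nuclei(field, density_per_mm2 = 0), "density")
})

test_that("FISH count simulation follows the binomial-plus-noise model", {
  p <- sim_params(n_rows = 10, n_cols = 10, n_genes = 10, seed = 2)
  field <- generate_clone_field(p)
  nuc <- simulate_nuclei(field, 2000, seed = 3)
  # perfect efficiency, no noise: counts equal the copy number
  f <- simulate_fish_counts(nuc, list(probe = c(A = 2, B = 2)),
                            efficiency = 1, false_rate = 0, seed = 1)
  expect_true(all(f$count == 2))
  # zero efficiency and noise: all zero
  f0 <- simulate_fish_counts(nuc, list(probe = c(A = 3, B = 1)),
                             efficiency = 0, false_rate = 0, seed = 1)
  expect_true(all(f0$count == 0))
  # CN 4 vs 2 at efficiency 0.9: means 3.6 and 1.8
  f2 <- simulate_fish_counts(nuc, list(probe = c(A = 4, B = 2)),
                             efficiency = 0.9, false_rate = 0, seed = 4)
  cl <- setNames(nuc$true_clone, nuc$nucleus_id)[f2$nucleus_id]
  expect_equal(mean(f2$count[cl == "A"]), 3.6, tolerance = 0.05)
  expect_equal(mean(f2$count[cl == "B"]), 1.8, tolerance = 0.05)
  expect_error(simulate_fish_counts(nuc, list(p = c(A = 2, B = 2)),
                                    efficiency = 1.2), "efficiency")
})

test_that("structure tables are reproducible and filterable as parameterised", {
  s1 <- simulate_structure_table(seed = 9)
  s2 <- simulate_structure_table(seed = 9)
  expect_identical(s1, s2)
  expect_equal(unique(s1$crop_id), 1:3)
  expect_equal(attr(s1, "crop_um"), 400)

  # 30% of cell areas below 10: filtered count ~ 70% of generated
  mix_dist <- function(n) {
    small <- stats::rbinom(n, 1, 0.3) == 1
    ifelse(small, stats::runif(n, 1, 9.9), stats::runif(n, 10.1, 80))
  }
  s3 <- simulate_structure_table(n_crops = 10, cell_area_dist = mix_dist,
                                 counts_per_crop = c(cell = 200,
                                                     microtube = 10),
                                 seed = 10)
  kept <- filter_structures(s3)
  frac <- sum(kept$class == "cell") / sum(s3$class == "cell")
  expect_equal(frac, 0.7, tolerance = 0.05)
})
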