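test_that("clone-informative genes are those overlapping differing CNV regions", {
  ann <- tibble::tibble(
    gene_id = c("g_chr8", "g_chr12", "g_chr1", "g_straddle"),
    chromosome = c("chr8", "chr12", "chr1", "chr8"),
    start = c(100, 100, 100, 950),
    end = c(200, 200, 200, 1100)
  )
  prof <- tibble::tibble(
    clone = rep(c("A", "B"), each = 3),
    chromosome = rep(c("chr1", "chr8", "chr12"), 2),
    start = 0, end = 1000,
    copy_number = c(2, 4, 4, 2, 2, 2)
  )
  genes <- select_clone_genes(ann, prof)
  expect_setequal(genes, c("g_chr8", "g_chr12", "g_straddle"))

  # identical profiles: indistinguishable clones
  prof_same <- dplyr::mutate(prof, copy_number = 2)
  expect_error(select_clone_genes(ann, prof_same), "indistinguishable")

  # sub-chromosomal difference: only overlapping genes selected
  prof_seg <- tibble::tibble(
    clone = c("A", "B"), chromosome = "chr8",
    start = c(150, 150), end = c(1000, 1000), copy_number = c(4, 2)
  )
  expect_setequal(select_clone_genes(ann, prof_seg),
                  c("g_chr8", "g_straddle"))
})

test_that("clone scores average normalized expression over the gene set", {
  counts <- matrix(1L, 2, 3, dimnames = list(c("s1", "s2"),
                                             c("g1", "g2", "g3")))
  pos <- tibble::tibble(barcode = c("s1", "s2"), in_tissue = 1L,
                        array_row = 0L, array_col = 0:1,
                        x_um = c(0, 100), y_um = 0)
  ds <- spot_dataset(counts, pos)
  ds$normalized <- Matrix::Matrix(rbind(c(1, 2, 3), c(4, 4, 4)),
                                  sparse = TRUE,
                                  dimnames = dimnames(counts))
  sc <- compute_clone_score(ds, c("g1", "g2", "g3"))
  expect_equal(sc$clone_score, c(2, 4))
  expect_error(compute_clone_score(ds, character()), "empty")
  expect_error(compute_clone_score(ds, "nope"), "no informative gene")
})

test_that("concordance is permutation invariant and ~0.5 for random labels", {
  l <- rep(c("A", "B"), 10)
  expect_equal(concordance(l, l), 1)
  expect_equal(concordance(l, ifelse(l == "A", "B", "A")), 1)
  withr::with_seed(1, {
    r <- mean(replicate(200, concordance(sample(c(1, 2), 400, TRUE),
                                         sample(c(1, 2), 400, TRUE))))
  })
  # max over the 2 pairings of a ~Binomial(400, .5)/400 agreement: ~0.52
  expect_lt(abs(r - 0.52), 0.015)
  expect_error(concordance(l, l[-1]), "length")
})

test_that("clone mapping recovers a synthetic half-split sample", {
  s <- small_mapped_sample(seed = 31)
  cm <- map_clones(s$ds, s$truth$annotation, s$truth$cnv_profiles, s$graph,
                   seed = 1)
  acc <- clone_accuracy(cm, s$true_clone)
  expect_gte(acc$accuracy, 0.95)
  # polarity: clone A is the gained, higher-scoring clone
  gl <- glance(cm)
  expect_gt(gl$mean_score_A, gl$mean_score_B)
  expect_gte(cm$concordance, 0.7)
  # tidy() exposes one row per spot
  expect_equal(nrow(tidy(cm)), n_spots(s$ds))
})

test_that("clone mapping is invariant to gene and spot order permutations", {
  s <- small_mapped_sample(seed = 32, n = 8, genes = 150, informative = 40)
  cm <- map_clones(s$ds, s$truth$annotation, s$truth$cnv_profiles, s$graph,
                   seed = 1)
  ds2 <- s$ds
  withr::with_seed(2, {
    gp <- sample(n_genes(s$ds))
    sp <- sample(n_spots(s$ds))
  })
  ds2$counts <- ds2$counts[sp, gp]
  ds2$normalized <- ds2$normalized[sp, gp]
  cm2 <- map_clones(ds2, s$truth$annotation, s$truth$cnv_profiles,
                    build_spot_graph(ds2), seed = 1)
  joined <- dplyr::inner_join(cm$assignments, cm2$assignments,
                              by = "spot_id")
  expect_equal(concordance(joined$clone.x, joined$clone.y), 1)
})

test_that("dosage-free data yields no stable polarity or chance accuracy", {
  accs <- vapply(33:37, function(sd) {
    s <- small_mapped_sample(seed = sd, n = 8, genes = 150,
                             informative = 40, contamination = 1)
    res <- tryCatch(
      map_clones(s$ds, s$truth$annotation, s$truth$cnv_profiles, s$graph,
                 seed = 1),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      expect_match(conditionMessage(res), "polarity|collapsed")
      NA_real_
    } else {
      clone_accuracy(res, s$true_clone)$accuracy
    }
  }, numeric(1))
  # with the dosage cancelled the polarity is arbitrary: accuracy ~ chance
  expect_lt(abs(mean(accs, na.rm = TRUE) - 0.5), 0.2)
})

test_that("FISH validation separates clones with different copy numbers", {
  p <- sim_params(n_rows = 12, n_cols = 12, n_genes = 10, seed = 41)
  field <- generate_clone_field(p)
  nuc <- simulate_nuclei(field, 1500, seed = 42)
  nuc$clone <- nuc$true_clone
  fish <- simulate_fish_counts(nuc, list(cen8 = c(A = 4, B = 2),
                                         MDM2 = c(A = 4, B = 2)),
                               efficiency = 0.9, seed = 43)
  fv <- validate_with_fish(nuc, fish)
  expect_setequal(fv$tests$probe, c("cen8", "MDM2"))
  expect_true(all(fv$tests$p < 0.01))
  expect_true(all(fv$tests$reliable))
  # distributions sum to one within clone x probe
  sums <- fv$distribution |>
    dplyr::group_by(clone, probe) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-12))
  # clone A shifted to higher signal counts (missing categories count as 0)
  frac4 <- function(cl) {
    hit <- fv$distribution$clone == cl & fv$distribution$probe == "cen8" &
      fv$distribution$signals == "4+"
    if (any(hit)) fv$distribution$fraction[hit] else 0
  }
  expect_gt(frac4("A"), frac4("B"))

  # degenerate: one nucleus per clone -> report produced, p flagged NA
  tiny <- nuc[c(which(nuc$true_clone == "A")[1],
                which(nuc$true_clone == "B")[1]), ]
  fv_tiny <- validate_with_fish(tiny,
                                dplyr::filter(fish,
                                              nucleus_id %in%
                                                tiny$nucleus_id))
  expect_false(any(fv_tiny$tests$reliable))
  expect_true(all(is.na(fv_tiny$tests$p)))
})
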