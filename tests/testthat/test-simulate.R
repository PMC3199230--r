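test_that("simulation is deterministic in the seed and sensitive to it", {
  a <- simulateCohort(SimulationConfig(n_features = 200, n_diff = 30,
                                       n_batch = 20, seed = 5))
  b <- simulateCohort(SimulationConfig(n_features = 200, n_diff = 30,
                                       n_batch = 20, seed = 5))
  c <- simulateCohort(SimulationConfig(n_features = 200, n_diff = 30,
                                       n_batch = 20, seed = 6))
  expect_identical(SummarizedExperiment::assay(a$se),
                   SummarizedExperiment::assay(b$se))
  expect_false(identical(SummarizedExperiment::assay(a$se),
                         SummarizedExperiment::assay(c$se)))
  validateExpression <- getFromNamespace("validateExpression", "bprsig")
  expect_true(validateExpression(a$se))
})

test_that("generated cohorts have the configured design structure", {
  sim <- simulateCohort(SimulationConfig(n_features = 100, n_diff = 20,
                                         n_batch = 10, seed = 2))
  ph <- colPheno(sim$se)
  expect_equal(sum(ph$phenotype == 1L), 17L)   # 6 pairs + 5 singletons
  expect_equal(sum(ph$phenotype == 0L), 6L)
  expect_equal(length(unique(ph$patient_id[ph$phenotype == 1L])), 11L)
  expect_equal(sum(table(ph$patient_id[ph$phenotype == 1L]) == 2L), 6L)
  expect_equal(length(unique(
    ph$patient_id[ph$sample_type == "explant"])), 5L)
  # truth is a subset of generated features, annotation fraction respected
  expect_true(all(names(sim$truth@diff_effects) %in% rownames(sim$se)))
  frac_ann <- mean(lengths(annotation(sim$se)) > 0)
  expect_gt(frac_ann, 0.8); expect_lt(frac_ann, 0.98)
})

test_that("null configuration gives equal group means", {
  sim <- simulateCohort(SimulationConfig(
    n_features = 300, effect_size = 0, batch_effect = 0,
    within_patient_rho = 0, noise_sd = 1e-4, baseline_sd = 1, seed = 3))
  m <- SummarizedExperiment::assay(sim$se)
  ph <- colPheno(sim$se)
  gap <- rowMeans(m[, ph$phenotype == 1L]) -
    rowMeans(m[, ph$phenotype == 0L])
  expect_lt(max(abs(gap)), 1e-3)
})

test_that("case-minus-control recovers the signed effect sizes", {
  n1 <- 20L; n0 <- 20L; ndiff <- 100L; sigma <- 1; delta <- 2
  sim <- simulateCohort(SimulationConfig(
    n_features = 1000, n_diff = ndiff, n_batch = 0L, n_cases = n1,
    n_controls = n0, frac_paired_lobes = 0, frac_explant = 0,
    effect_size = delta, within_patient_rho = 0, noise_sd = sigma,
    seed = 9))
  m <- SummarizedExperiment::assay(sim$se)
  ph <- colPheno(sim$se)
  eff <- sim$truth@diff_effects
  gap <- rowMeans(m[names(eff), ph$phenotype == 1L]) -
    rowMeans(m[names(eff), ph$phenotype == 0L])
  # mean over sign-corrected gaps ~ N(delta, sigma^2 (1/n1 + 1/n0) / ndiff)
  est <- mean(gap * sign(eff))
  half99 <- 2.576 * sigma * sqrt((1 / n1 + 1 / n0) / ndiff)
  expect_lt(abs(est - delta), half99)
})

test_that("lobe pairs correlate through the shared patient effect", {
  sim <- simulateCohort(SimulationConfig(
    n_features = 800, effect_size = 0, batch_effect = 0, baseline_sd = 0,
    within_patient_rho = 0.7, seed = 4))
  m <- SummarizedExperiment::assay(sim$se)
  ph <- colPheno(sim$se)
  pairs <- names(which(table(ph$patient_id[ph$phenotype == 1L]) == 2L))
  rs <- vapply(pairs, function(p) {
    idx <- which(ph$patient_id == p)
    cor(m[, idx[1L]], m[, idx[2L]])
  }, numeric(1))
  # residual correlation should concentrate near rho = 0.7
  expect_gt(mean(rs), 0.6)
  expect_lt(mean(rs), 0.8)
})

test_that("large batch effect separates explants from biopsies on PC1", {
  skip_if_not_installed("cluster")
  sim <- simulateCohort(SimulationConfig(
    n_features = 600, n_diff = 0L, n_batch = 150L, effect_size = 0,
    batch_effect = 3, within_patient_rho = 0, seed = 8))
  ph <- colPheno(sim$se)
  cases <- ph$phenotype == 1L
  pca <- expressionPCA(sim$se[, cases], n_components = 1L)
  lab <- as.integer(ph$sample_type[cases] == "explant") + 1L
  sil <- cluster::silhouette(lab, dist(pca$scores[, 1L]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("second-platform simulation respects the mapping spec", {
  sim <- simulateCohort(SimulationConfig(n_features = 400, seed = 10))
  # identity spec: all one-to-one, no distortion or noise
  id <- simulateSecondPlatform(sim$se, frac_one_to_one = 1,
                               frac_many_to_one = 0, frac_one_to_many = 0,
                               drop_frac = 0, scale_sd = 0, shift_sd = 0,
                               noise_sd = 0, seed = 1)
  expect_equal(nrow(id$se), 400L)
  src <- SummarizedExperiment::assay(sim$se)[id$mapping$train_id, ]
  dst <- SummarizedExperiment::assay(id$se)[id$mapping$val_id, ]
  expect_equal(unname(dst), unname(src), tolerance = 1e-12)

  # dropped features: binomial 99% interval around drop_frac
  big <- simulateCohort(SimulationConfig(n_features = 1000, seed = 11))
  dp <- simulateSecondPlatform(big$se, frac_one_to_one = 0.98,
                               frac_many_to_one = 0, frac_one_to_many = 0,
                               drop_frac = 0.02, seed = 2)
  n_mapped <- length(unique(dp$mapping$train_id))
  half99 <- 2.576 * sqrt(1000 * 0.02 * 0.98)
  expect_lt(abs((1000 - n_mapped) - 20), half99 + 1)

  # one-to-many children are affine images of one parent: r = 1 at no noise
  om <- simulateSecondPlatform(sim$se, frac_one_to_one = 0,
                               frac_many_to_one = 0, frac_one_to_many = 1,
                               drop_frac = 0, noise_sd = 0, seed = 3)
  kids <- split(om$mapping$val_id, om$mapping$train_id)
  expect_true(all(lengths(kids) == 2L))
  v <- SummarizedExperiment::assay(om$se)
  r12 <- cor(v[kids[[1L]][1L], ], v[kids[[1L]][2L], ])
  expect_equal(r12, 1, tolerance = 1e-12)

  expect_error(simulateSecondPlatform(sim$se, frac_one_to_one = 0.9,
                                      frac_many_to_one = 0.2,
                                      frac_one_to_many = 0,
                                      drop_frac = 0), "sum to at most 1")
})

test_that("invalid configurations fail before any sampling", {
  expect_error(SimulationConfig(frac_explant = 1.2), "frac")
  expect_error(SimulationConfig(noise_sd = 0), "noise_sd")
  expect_error(SimulationConfig(n_features = 100, n_diff = 90, n_batch = 20),
               "n_diff")
  expect_error(SimulationConfig(within_patient_rho = 1), "rho")
})
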