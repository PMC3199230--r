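test_that("pearson distance matches the direct formula and its limits", {
  set.seed(3)
  m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("g", 1:4),
                                               c("a", "b", "c")))
  d <- pearsonDistance(m)
  # direct formula, written out
  r_ab <- sum((m[, 1] - mean(m[, 1])) * (m[, 2] - mean(m[, 2]))) /
    sqrt(sum((m[, 1] - mean(m[, 1]))^2) * sum((m[, 2] - mean(m[, 2]))^2))
  expect_equal(d["a", "b"], 1 - r_ab, tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d, t(d))

  dup <- cbind(m, a2 = m[, "a"])
  rownames(dup) <- rownames(m)
  expect_equal(pearsonDistance(dup)["a", "a2"], 0, tolerance = 1e-12)
  neg <- cbind(m, aneg = -m[, "a"])
  rownames(neg) <- rownames(m)
  expect_equal(pearsonDistance(neg)["a", "aneg"], 2, tolerance = 1e-12)
  # invariant under positive affine rescaling of a sample
  m2 <- m; m2[, 2] <- 3 * m2[, 2] + 10
  expect_equal(pearsonDistance(m2), d, tolerance = 1e-12)
  flat <- m; flat[, 2] <- 1
  expect_error(pearsonDistance(flat), "b")
})

test_that("UPGMA reproduces the hand-worked three-leaf dendrogram", {
  D <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- averageLinkage(D)
  expect_equal(hc$height, c(1, 4.5))
  expect_identical(hc$merge[1, ], c(-2L, -1L))
  # identical leaves merge first at height zero
  D0 <- matrix(c(0, 0, 2, 0, 0, 2, 2, 2, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  hc0 <- averageLinkage(D0)
  expect_equal(hc0$height[1], 0)
  expect_error(averageLinkage(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("UPGMA agrees with brute-force agglomeration and hclust", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:7, 1)
    m <- matrix(rnorm(n * 10), 10, n,
                dimnames = list(NULL, paste0("s", seq_len(n))))
    D <- 1 - cor(m); diag(D) <- 0
    hc <- averageLinkage(D)
    # heights never decrease for average linkage
    expect_true(!is.unsorted(hc$height))
    ref <- bruteUPGMA(D)
    expect_equal(hc$height, ref$heights, tolerance = 1e-12)
    for (s in seq_len(n - 2L))
      expect_identical(canonicalPartition(hclustPartition(hc, s)),
                       canonicalPartition(ref$partitions[[s]]))
    # independent implementation cross-check (tie-free random input)
    hc2 <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(sort(hc$height), sort(hc2$height), tolerance = 1e-12)
  }
})

test_that("newick export writes an ape-readable ultrametric tree", {
  se <- randomSE(20, 6, seed = 2)
  hc <- averageLinkage(pearsonDistance(se))
  f <- tempfile(fileext = ".nwk")
  exportNewick(hc, f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, colnames(se))
})

test_that("PCA variance accounting and reconstruction are exact", {
  # rank-1 matrix: all variance on the first component
  u <- rnorm(8); v <- rnorm(5)
  m1 <- outer(u, v)
  dimnames(m1) <- list(paste0("g", 1:8), paste0("s", 1:5))
  p1 <- expressionPCA(m1, n_components = 1L)
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-10)

  se <- randomSE(15, 8, seed = 4)
  m <- SummarizedExperiment::assay(se)
  full <- expressionPCA(se, n_components = 7L)
  expect_equal(sum(full$variance_explained), 1, tolerance = 1e-12)
  expect_true(all(diff(full$variance_explained) < 1e-12))
  # reconstruction from all components reproduces the centered data
  rec <- full$scores %*% t(full$loadings)
  cen <- t(m - rowMeans(m))
  expect_equal(unname(rec), unname(cen), tolerance = 1e-8)
  expect_error(expressionPCA(se, n_components = 10L), "n_components")
})

test_that("isotropic data splits variance evenly across two components", {
  set.seed(11)
  m <- matrix(rnorm(2 * 4000), 2, 4000,
              dimnames = list(c("g1", "g2"), paste0("s", 1:4000)))
  p <- expressionPCA(m, n_components = 2L)
  expect_equal(p$variance_explained[1], 0.5, tolerance = 0.05)
})

test_that("matched lobe pairs correlate more than unmatched samples", {
  sim <- simulateCohort(SimulationConfig(
    n_features = 500, baseline_sd = 1, within_patient_rho = 0.9,
    effect_size = 0, batch_effect = 0, seed = 6))
  pc <- pairedCorrelation(sim$se)
  expect_gt(pc$matched, pc$unmatched)
  expect_equal(pc$n_pairs, 6L)
  # identical columns give matched r of exactly 1
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m[, 2] <- m[, 1]
  ph <- data.frame(sample_id = colnames(m), phenotype = 1L,
                   patient_id = c("p1", "p1", "p2", "p3"),
                   lobe = c("upper", "lower", "upper", "upper"),
                   sample_type = "biopsy")
  pc2 <- pairedCorrelation(toySE(m, pheno = ph))
  expect_equal(pc2$matched, 1, tolerance = 1e-12)
  # under rho = 0 the two averages coincide within sampling noise
  sim0 <- simulateCohort(SimulationConfig(
    n_features = 2000, baseline_sd = 1, within_patient_rho = 0,
    effect_size = 0, batch_effect = 0, seed = 7))
  pc0 <- pairedCorrelation(sim0$se)
  expect_lt(abs(pc0$matched - pc0$unmatched), 0.1)
})

test_that("one-way ICC matches hand ANOVA arithmetic", {
  # 4 groups x 2 members, worked through the ANOVA table directly
  vals <- c(1.0, 1.4, 2.0, 2.6, 3.1, 2.9, 0.2, 0.6)
  grp <- rep(c("a", "b", "c", "d"), each = 2)
  g <- 4; k <- 2
  gm <- tapply(vals, grp, mean)
  msb <- k * sum((gm - mean(vals))^2) / (g - 1)
  msw <- sum((vals - rep(gm, each = k))^2) / (g * (k - 1))
  ref_icc <- (msb - msw) / (msb + (k - 1) * msw)
  ref_p <- pf(msb / msw, g - 1, g * (k - 1), lower.tail = FALSE)
  got <- iccOneWay(vals, grp)
  expect_equal(got$icc, ref_icc, tolerance = 1e-12)
  expect_equal(got$p_value, ref_p, tolerance = 1e-12)

  # identical members in every group: ICC exactly 1
  ident <- iccOneWay(rep(c(1, 5, 9), each = 2), rep(1:3, each = 2))
  expect_equal(ident$icc, 1)
  expect_error(iccOneWay(1:5, c(1, 1, 2, 2, 2)), "balanced")
})

test_that("ICC is centered at zero when group labels are random", {
  set.seed(21)
  iccs <- replicate(200, {
    vals <- rnorm(12)
    iccOneWay(vals, sample(rep(1:6, each = 2)))$icc
  })
  expect_lt(abs(mean(iccs)), 0.1)
})
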