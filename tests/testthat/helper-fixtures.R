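# Shared fixtures, built in code at test time.

# Small expression container with explicit values and annotation.
toySE <- function(values, annotation = NULL, pheno = NULL) {
  cohortExperiment(values, annotation = annotation, pheno = pheno)
}

# Random annotated matrix: every feature gets a gene ID.
randomSE <- function(n_features, n_samples, seed = 1,
                     annotate = TRUE) {
  set.seed(seed)
  m <- matrix(rnorm(n_features * n_samples, 7, 2), n_features, n_samples,
              dimnames = list(sprintf("g%03d", seq_len(n_features)),
                              sprintf("s%02d", seq_len(n_samples))))
  ann <- if (annotate) {
    a <- as.list(sprintf("GENE%03d", seq_len(n_features)))
    names(a) <- rownames(m)
    a
  } else NULL
  cohortExperiment(m, annotation = ann)
}

table1Path <- function() {
  system.file("extdata", "table1_cohort.tsv", package = "bprsig")
}

table1Pheno <- function() readPhenotypeTable(table1Path())

# Small two-class cohort for classifier tests.
smallCohort <- function(seed = 1, n_features = 400, n_diff = 60,
                        delta = 2.5, rho = 0, ...) {
  simulateCohort(SimulationConfig(
    n_features = n_features, n_diff = n_diff, n_batch = 20L,
    effect_size = delta, within_patient_rho = rho, seed = seed, ...))
}

colPheno <- function(se) as.data.frame(SummarizedExperiment::colData(se))

# Independent brute-force UPGMA: at every step enumerate all cluster pairs,
# merge the closest (ties by smallest sorted representative-label pair).
# Returns merge heights and the leaf partition after each step.
bruteUPGMA <- function(D, labels = rownames(D)) {
  clus <- lapply(seq_len(nrow(D)), function(i) i)
  reps <- labels
  heights <- numeric(0)
  partitions <- list()
  while (length(clus) > 1L) {
    best <- NULL
    for (i in seq_len(length(clus) - 1L)) for (j in (i + 1L):length(clus)) {
      d <- mean(D[clus[[i]], clus[[j]]])
      pr <- sort(c(reps[i], reps[j]))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (pr[1L] < best$pr[1L] ||
            (pr[1L] == best$pr[1L] && pr[2L] < best$pr[2L]))))
        best <- list(i = i, j = j, d = d, pr = pr)
    }
    heights <- c(heights, best$d)
    clus[[best$i]] <- c(clus[[best$i]], clus[[best$j]])
    reps[best$i] <- min(reps[best$i], reps[best$j])
    clus[[best$j]] <- NULL
    reps <- reps[-best$j]
    partitions[[length(partitions) + 1L]] <-
      lapply(clus, function(m) sort(labels[m]))
  }
  list(heights = heights, partitions = partitions)
}

# Leaf partition of an hclust tree after s merges (n - s clusters).
hclustPartition <- function(hc, s) {
  k <- length(hc$labels) - s
  grp <- stats::cutree(hc, k = k)
  unname(lapply(split(names(grp), grp), sort))
}

# Canonical form of a partition (sorted list of sorted member vectors).
canonicalPartition <- function(p) {
  p <- lapply(p, sort)
  p[order(vapply(p, `[`, "", 1L))]
}

# Independent step-up FDR adjustment, written from the definition.
bruteBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    j <- which(o == i)   # rank of p[i]
    q[i] <- min(1, min(n / seq(j, n) * sort(p)[seq(j, n)]))
  }
  q
}

# Independent AUC by pair counting with ties at 1/2.
bruteAUC <- function(probs, labels) {
  cs <- probs[labels == 1]
  ct <- probs[labels == 0]
  s <- 0
  for (a in cs) for (b in ct)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cs) * length(ct))
}
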