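# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: a log2 baseline per feature, a signed case/control shift on a
# differential subset, an explant batch shift, a shared per-patient effect
# inducing lobe-pair correlation, and i.i.d. Gaussian noise.

#' Simulate a two-group whole-lung expression cohort
#'
#' Draws a cohort under a [SimulationConfig-class]. Cases may contribute an
#' upper/lower lobe pair (sharing a per-patient random effect), a fraction
#' of case patients are labeled explants and receive an extra shift on a
#' batch-feature subset, and a fraction of features carry synthetic gene
#' annotation. Deterministic for a fixed seed; independent named substreams
#' drive the baseline, the design and the noise so the stages do not perturb
#' one another.
#'
#' @param config a [SimulationConfig-class].
#' @param truth optional [SimulationTruth-class] from a previous call: reuse
#'   its baselines, effects and annotation so the new cohort is drawn from
#'   the same population (e.g. an independent validation cohort).
#' @return list with elements `se` (SummarizedExperiment with phenotype in
#'   `colData`) and `truth` ([SimulationTruth-class]).
#' @examples
#' sim <- simulateCohort(SimulationConfig(n_features = 300, seed = 1))
#' dim(sim$se)
#' table(SummarizedExperiment::colData(sim$se)$sample_type)
#' @export
simulateCohort <- function(config, truth = NULL) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  p <- config@n_features
  feat <- sprintf("FEAT%06d", seq_len(p))

  if (is.null(truth)) {
    truth <- withSeed(substreamSeed(config@seed, "baseline"), {
      baseline <- setNames(
        rnorm(p, config@baseline_mean, config@baseline_sd), feat)
      idx <- sample.int(p, config@n_diff + config@n_batch)
      diff_idx <- idx[seq_len(config@n_diff)]
      batch_idx <- idx[config@n_diff + seq_len(config@n_batch)]
      signs <- sample(c(-1, 1), config@n_diff, replace = TRUE)
      ann <- rep(list(character(0)), p)
      names(ann) <- feat
      annotated <- runif(p) < config@frac_annotated
      ann[annotated] <- as.list(sprintf("GENE%06d", which(annotated)))
      new("SimulationTruth", baseline = baseline,
          diff_effects = setNames(signs * config@effect_size,
                                  feat[diff_idx]),
          batch_features = feat[batch_idx], annotation = ann)
    })
  } else {
    stopifnot(is(truth, "SimulationTruth"))
    if (length(truth@baseline) != p)
      stop("truth was generated for ", length(truth@baseline),
           " features, config asks for ", p)
    feat <- names(truth@baseline)
  }

  design <- withSeed(substreamSeed(config@seed, "design"), {
    n_pair <- round(config@frac_paired_lobes * config@n_cases)
    n_expl <- round(config@frac_explant * config@n_cases)
    paired <- seq_len(config@n_cases) %in%
      sample.int(config@n_cases, n_pair)
    explant <- seq_len(config@n_cases) %in%
      sample.int(config@n_cases, n_expl)
    rows <- list()
    for (i in seq_len(config@n_cases)) {
      type <- if (explant[i]) "explant" else "biopsy"
      stem <- sprintf("%s_%03d", if (explant[i]) "Explant" else "Biopsy",
                      100L + i)
      pid <- sprintf("CASE%02d", i)
      lobes <- if (paired[i]) c("upper", "lower") else "upper"
      for (lb in lobes)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste0(stem, toupper(substr(lb, 1, 1))),
          phenotype = 1L, patient_id = pid, lobe = lb, sample_type = type,
          stringsAsFactors = FALSE)
    }
    for (i in seq_len(config@n_controls))
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("Normal_%02d", i), phenotype = 0L,
        patient_id = sprintf("CTRL%02d", i), lobe = "unknown",
        sample_type = "control", stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })

  n <- nrow(design)
  effect <- setNames(numeric(p), feat)
  effect[names(truth@diff_effects)] <- truth@diff_effects
  batch <- setNames(numeric(p), feat)
  batch[truth@batch_features] <- config@batch_effect

  rho <- config@within_patient_rho
  pat_sd <- config@noise_sd * sqrt(rho / (1 - rho))
  X <- withSeed(substreamSeed(config@seed, "noise"), {
    patients <- unique(design$patient_id)
    pat_eff <- matrix(rnorm(p * length(patients), 0, pat_sd), p,
                      dimnames = list(feat, patients))
    noise <- matrix(rnorm(p * n, 0, config@noise_sd), p)
    mu <- truth@baseline +
      outer(effect, design$phenotype) +
      outer(batch, as.numeric(design$sample_type == "explant"))
    mu + pat_eff[, design$patient_id] + noise
  })
  colnames(X) <- design$sample_id

  se <- cohortExperiment(X, annotation = truth@annotation, pheno = design)
  list(se = se, truth = truth)
}

#' Simulate a second microarray platform
#'
#' Re-measures a cohort on a second platform whose features are affine-
#' distorted copies of mapped source features plus noise, linked to the
#' source platform by a many-by-many feature mapping. Each source feature is
#' randomly assigned a mapping category: one-to-one, many-to-one (two source
#' features averaged into one target), one-to-many (two targets per source)
#' or dropped (no link, emulating unmapped probes).
#'
#' @param se source-platform SummarizedExperiment.
#' @param frac_one_to_one,frac_many_to_one,frac_one_to_many,drop_frac
#'   category probabilities; must sum to 1 (at most 1, remainder treated
#'   as one-to-one).
#' @param scale_sd SD of the per-target log scale factor (`a = exp(N(0,
#'   scale_sd))`, so 0 means scale 1).
#' @param shift_sd SD of the per-target additive shift (log2 units).
#' @param noise_sd SD of per-measurement platform noise.
#' @param seed integer seed.
#' @return list: `se` (second-platform SummarizedExperiment, gene annotation
#'   inherited from parents) and `mapping` (data.frame `train_id`,
#'   `val_id` of all links).
#' @export
simulateSecondPlatform <- function(se, frac_one_to_one = 0.80,
                                   frac_many_to_one = 0.09,
                                   frac_one_to_many = 0.09,
                                   drop_frac = 0.02,
                                   scale_sd = 0.15, shift_sd = 0.3,
                                   noise_sd = 0.1, seed = 1L) {
  fr <- c(frac_one_to_one, frac_many_to_one, frac_one_to_many, drop_frac)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12)
    stop("mapping fractions must be nonnegative and sum to at most 1")
  fr[1L] <- fr[1L] + max(0, 1 - sum(fr))
  X <- exprsMatrix(se)
  ann <- annotationList(se)
  p <- nrow(X)
  withSeed(substreamSeed(seed, "platform2"), {
    cat_ <- sample(c("o2o", "m2o", "o2m", "drop"), p, replace = TRUE,
                   prob = fr)
    parents <- list()  # one entry per target feature: parent row indices
    m2o <- which(cat_ == "m2o")
    if (length(m2o) %% 2L == 1L) {   # odd leftover behaves one-to-one
      cat_[m2o[length(m2o)]] <- "o2o"
      m2o <- m2o[-length(m2o)]
    }
    for (i in which(cat_ == "o2o")) parents[[length(parents) + 1L]] <- i
    if (length(m2o))
      for (j in seq(1L, length(m2o), by = 2L))
        parents[[length(parents) + 1L]] <- m2o[c(j, j + 1L)]
    for (i in which(cat_ == "o2m")) {
      parents[[length(parents) + 1L]] <- i
      parents[[length(parents) + 1L]] <- i
    }
    q <- length(parents)
    val_ids <- sprintf("AGFT%06d", seq_len(q))
    a <- exp(rnorm(q, 0, scale_sd))
    b <- rnorm(q, 0, shift_sd)
    V <- matrix(NA_real_, q, ncol(X), dimnames = list(val_ids, colnames(X)))
    ann_val <- vector("list", q)
    links <- vector("list", q)
    for (t in seq_len(q)) {
      src <- parents[[t]]
      base <- if (length(src) == 1L) X[src, ] else colMeans(X[src, ])
      V[t, ] <- a[t] * base + b[t] + rnorm(ncol(X), 0, noise_sd)
      ann_val[[t]] <- unique(unlist(ann[src], use.names = FALSE))
      links[[t]] <- data.frame(train_id = rownames(X)[src],
                               val_id = val_ids[t],
                               stringsAsFactors = FALSE)
    }
    names(ann_val) <- val_ids
    mapping <- do.call(rbind, links)
    pheno <- phenoFrame(se)
    se2 <- cohortExperiment(V, annotation = ann_val,
                            pheno = if (ncol(pheno)) pheno else NULL)
    list(se = se2, mapping = mapping)
  })
}
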