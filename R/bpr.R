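# The core classifier: SVD metagene factors, Bayesian probit regression by
# latent-variable Gibbs sampling (data augmentation with truncated-normal
# latents and a conjugate Gaussian coefficient update), posterior predictive
# probabilities, and leave-one-out model-size tuning.

#' Build SVD metagene factors from a training matrix
#'
#' Selects the top-`k` features by absolute pooled Student t, standardizes
#' each selected feature by its training mean and SD, and decomposes the
#' standardized k x n matrix `X = U S V'`. The first `r` right singular
#' vectors are the per-sample factor scores; equivalently the score of a
#' sample with standardized profile `x` is `S^-1 U' x`.
#'
#' @param se SummarizedExperiment or matrix (features x samples).
#' @param y binary 0/1 labels.
#' @param k number of features in the panel.
#' @param r number of factors (default 2).
#' @return list: `features`, `center`, `scale`, `loadings` (k x r),
#'   `singular_values` (r), `scores` (n x r).
#' @export
buildFactors <- function(se, y, k, r = 2L) {
  m <- exprsMatrix(se)
  if (k > nrow(m))
    stop("k = ", k, " exceeds available features (", nrow(m), ")")
  if (r > min(k, ncol(m))) stop("r must be at most min(k, samples)")
  st <- .pooledT(m, as.integer(y), min_per_class = 1L)
  ord <- order(-abs(st$t), seq_along(st$t))
  features <- rownames(m)[ord][seq_len(k)]
  sub <- m[features, , drop = FALSE]
  center <- rowMeans(sub)
  scale <- apply(sub, 1, sd)
  if (any(scale == 0))
    stop("zero-variance selected feature: ", features[scale == 0][1L])
  xs <- (sub - center) / scale
  sv <- svd(xs, nu = r, nv = r)
  list(features = features, center = center, scale = scale,
       loadings = sv$u, singular_values = sv$d[seq_len(r)],
       scores = sv$v)
}

# Project standardized profiles (k x m) into factor space using training
# loadings; with all k rows present this is S^-1 U' x = rows of V.
.projectScores <- function(xs, loadings, d) {
  r <- length(d)
  if (nrow(xs) < r)
    stop("fewer available features (", nrow(xs), ") than factors (", r, ")")
  g <- qr.solve(loadings, xs)              # least squares, exact when full
  t(g / d)                                 # m x r
}

#' Fit a Bayesian probit regression by Gibbs sampling
#'
#' Model: `Pr(y = 1) = Phi(b0 + f' b)` with prior
#' `beta ~ N(0, diag(prior))`. Sampled by Albert-Chib data augmentation:
#' latent `z_i | beta ~ N(w_i' beta, 1)` truncated positive for cases and
#' negative for controls, then a conjugate multivariate normal update of
#' `beta`. Deterministic for a fixed seed.
#'
#' @param F factor scores, n x r matrix.
#' @param y binary 0/1 labels, both classes present.
#' @param prior prior variances of (intercept, coefficients); a scalar pair
#'   `c(var_intercept, var_coef)` is expanded across factors.
#' @param iterations,burn_in MCMC settings; `iterations - burn_in` draws
#'   are retained.
#' @param seed integer RNG seed.
#' @return list of class data: `draws` ((iterations - burn_in) x (r + 1)
#'   matrix, intercept first), `prior`, `mcmc` settings.
#' @export
fitBPR <- function(F, y, prior = c(100, 4), iterations = 10000L,
                   burn_in = 2000L, seed = 1L) {
  F <- as.matrix(F)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (!all(is.finite(F))) stop("non-finite factor scores")
  if (burn_in >= iterations) stop("burn_in must be below iterations")
  n <- nrow(F); r <- ncol(F)
  W <- cbind(1, F)
  pv <- if (length(prior) == 2L) c(prior[1L], rep(prior[2L], r))
        else prior
  if (length(pv) != r + 1L) stop("prior must give intercept + r variances")
  A <- crossprod(W) + diag(1 / pv, r + 1L)
  R <- chol(A)                              # A = R'R
  draws <- matrix(NA_real_, iterations - burn_in, r + 1L)
  withSeed(seed, {
    beta <- rep(0, r + 1L)
    for (it in seq_len(iterations)) {
      eta <- drop(W %*% beta)
      # truncated-normal latents by inverse CDF, clipped away from 0/1
      lo <- ifelse(y == 1L, pnorm(-eta), 0)
      hi <- ifelse(y == 1L, 1, pnorm(-eta))
      u <- pmin(pmax(lo + runif(n) * (hi - lo), 1e-12), 1 - 1e-12)
      z <- eta + qnorm(u)
      mu <- backsolve(R, backsolve(R, crossprod(W, z), transpose = TRUE))
      beta <- drop(mu + backsolve(R, rnorm(r + 1L)))
      if (it > burn_in) draws[it - burn_in, ] <- beta
    }
  })
  colnames(draws) <- c("intercept", paste0("factor", seq_len(r)))
  list(draws = draws, prior = pv,
       mcmc = list(iterations = as.integer(iterations),
                   burn_in = as.integer(burn_in), seed = as.integer(seed)))
}

#' Train a signature at a fixed panel size
#'
#' Full-data fit: feature ranking, standardization, SVD factors, then the
#' probit Gibbs sampler; everything needed to predict new samples is frozen
#' in the returned [SignatureModel-class].
#'
#' @param se SummarizedExperiment or matrix.
#' @param y binary 0/1 labels.
#' @param k panel size.
#' @param r number of factors (default 2).
#' @param prior,iterations,burn_in,seed passed to [fitBPR()].
#' @return a [SignatureModel-class].
#' @export
trainSignature <- function(se, y, k, r = 2L, prior = c(100, 4),
                           iterations = 10000L, burn_in = 2000L,
                           seed = 1L) {
  fb <- buildFactors(se, y, k, r)
  fit <- fitBPR(fb$scores, y, prior = prior, iterations = iterations,
                burn_in = burn_in, seed = seed)
  new("SignatureModel", features = fb$features, center = fb$center,
      scale = fb$scale, loadings = fb$loadings,
      singular_values = fb$singular_values, draws = fit$draws,
      k = as.integer(k), r = as.integer(r), prior = fit$prior,
      mcmc = fit$mcmc, labels = list(case = 1L, control = 0L))
}

#' Predict case probabilities for new samples
#'
#' Standardizes the model's features with the training center/scale,
#' projects onto the training SVD factors and averages `Phi(linear
#' predictor)` over the retained posterior draws (default), or evaluates
#' `Phi` at the posterior-mean coefficients.
#'
#' @param model a [SignatureModel-class].
#' @param se SummarizedExperiment or matrix containing all model features.
#' @param type `"posterior_mean_prob"` (mean of per-draw probabilities) or
#'   `"prob_at_mean"` (probability at the posterior-mean coefficients).
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predictProbability <- function(model, se,
                               type = c("posterior_mean_prob",
                                        "prob_at_mean")) {
  type <- match.arg(type)
  m <- exprsMatrix(se)
  missing <- setdiff(model@features, rownames(m))
  if (length(missing))
    stop("matrix lacks model features: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) " ..." else "")
  xs <- (m[model@features, , drop = FALSE] - model@center) / model@scale
  f <- .projectScores(xs, model@loadings, model@singular_values)
  .drawProbabilities(model@draws, f, type)
}

.drawProbabilities <- function(draws, f, type = "posterior_mean_prob") {
  W <- cbind(1, f)
  eta <- W %*% t(draws)                    # samples x draws
  if (type == "posterior_mean_prob") {
    p <- rowMeans(pnorm(eta))
  } else {
    p <- pnorm(drop(W %*% colMeans(draws)))
  }
  names(p) <- rownames(f)
  p
}

#' Leave-one-out evaluation at a fixed panel size
#'
#' For each held-out sample the full training procedure is re-run on the
#' remaining samples (feature ranking, standardization, SVD, probit fit),
#' then the held-out sample is predicted. Reports the sum of deviances
#' `sum(-2 [y log p + (1 - y) log(1 - p)])` with probabilities clipped to
#' `[1e-6, 1 - 1e-6]`, and the misclassification rate at the 0.5 threshold.
#' Fold `i` uses seed `seed + i`.
#'
#' @param se SummarizedExperiment or matrix.
#' @param y binary 0/1 labels; n >= 4 and at least two per class.
#' @param k panel size.
#' @param r,prior,iterations,burn_in,seed fit settings (defaults sized for
#'   repeated inner fits: 2000 iterations, 500 burn-in).
#' @return list: `sum_deviance`, `misclassification`, `probabilities`
#'   (held-out, in sample order).
#' @export
looEvaluate <- function(se, y, k, r = 2L, prior = c(100, 4),
                        iterations = 2000L, burn_in = 500L, seed = 1L) {
  m <- exprsMatrix(se)
  y <- as.integer(y)
  n <- ncol(m)
  if (n < 4L || sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("need n >= 4 with at least two samples per class")
  probs <- numeric(n)
  for (i in seq_len(n)) {
    y_tr <- y[-i]
    if (length(unique(y_tr)) < 2L)
      stop("fold ", i, " loses one class entirely")
    fb <- buildFactors(m[, -i, drop = FALSE], y_tr, k, r)
    fit <- fitBPR(fb$scores, y_tr, prior = prior, iterations = iterations,
                  burn_in = burn_in, seed = seed + i)
    xs <- (m[fb$features, i, drop = FALSE] - fb$center) / fb$scale
    f <- .projectScores(xs, fb$loadings, fb$singular_values)
    probs[i] <- .drawProbabilities(fit$draws, f)
  }
  names(probs) <- colnames(m)
  pc <- pmin(pmax(probs, 1e-6), 1 - 1e-6)
  dev <- -2 * (y * log(pc) + (1 - y) * log(1 - pc))
  list(sum_deviance = sum(dev),
       misclassification = mean((probs >= 0.5) != (y == 1L)),
       probabilities = probs, deviances = dev)
}

# Smallest k attaining the minimum deviance (ties toward smaller k).
.chooseK <- function(grid, deviances) {
  grid[which(deviances == min(deviances))[1L]]
}

#' Tune the signature panel size by leave-one-out deviance
#'
#' Runs [looEvaluate()] for every candidate size and selects the smallest
#' size attaining the minimum sum of deviances; the misclassification rate
#' is reported alongside for plotting.
#'
#' @param se SummarizedExperiment or matrix.
#' @param y binary 0/1 labels.
#' @param grid candidate panel sizes (default 50 to 250 in steps of 10).
#' @param r,prior,iterations,burn_in,seed passed to [looEvaluate()].
#' @return a [ModelSelectionTrace-class].
#' @export
tuneModelSize <- function(se, y, grid = seq(50L, 250L, by = 10L), r = 2L,
                          prior = c(100, 4), iterations = 2000L,
                          burn_in = 500L, seed = 1L) {
  if (!length(grid)) stop("empty model-size grid")
  m <- exprsMatrix(se)
  if (max(grid) > nrow(m))
    stop("grid maximum ", max(grid), " exceeds available features (",
         nrow(m), ")")
  grid <- sort(unique(as.integer(grid)))
  res <- lapply(grid, function(k)
    looEvaluate(m, y, k, r = r, prior = prior, iterations = iterations,
                burn_in = burn_in, seed = seed))
  tr <- data.frame(k = grid,
                   sum_deviance = vapply(res, `[[`, 1, "sum_deviance"),
                   misclassification = vapply(res, `[[`, 1,
                                              "misclassification"))
  new("ModelSelectionTrace", trace = tr,
      chosen_k = as.integer(.chooseK(grid, tr$sum_deviance)))
}

#' Write a trained signature to disk
#'
#' Plain-text serialization: a JSON envelope (settings, singular values,
#' labels) plus TSV blocks for the per-feature panel (center, scale,
#' loadings) and the posterior draws. Values are written with 17
#' significant digits so reloading reproduces predictions bit-for-bit.
#'
#' @param model a [SignatureModel-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSignatureModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(k = model@k, r = model@r, prior = model@prior,
               mcmc = model@mcmc, labels = model@labels,
               singular_values = sprintf("%.17g", model@singular_values),
               package_version = as.character(packageVersion("bprsig")))
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  feat <- data.frame(feature = model@features,
                     center = sprintf("%.17g", model@center),
                     scale = sprintf("%.17g", model@scale))
  L <- apply(model@loadings, 2, function(v) sprintf("%.17g", v))
  colnames(L) <- paste0("loading", seq_len(model@r))
  write.table(cbind(feat, L), file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  dr <- apply(model@draws, 2, function(v) sprintf("%.17g", v))
  write.table(dr, file.path(dir, "draws.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Read a trained signature from disk
#'
#' @param dir directory written by [writeSignatureModel()].
#' @return a [SignatureModel-class].
#' @export
readSignatureModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  feat <- read.delim(file.path(dir, "features.tsv"), sep = "\t",
                     colClasses = "character")
  dr <- as.matrix(read.delim(file.path(dir, "draws.tsv"), sep = "\t",
                             colClasses = "numeric"))
  r <- as.integer(meta$r)
  loadings <- as.matrix(sapply(seq_len(r), function(j)
    as.numeric(feat[[paste0("loading", j)]])))
  new("SignatureModel", features = feat$feature,
      center = setNames(as.numeric(feat$center), feat$feature),
      scale = setNames(as.numeric(feat$scale), feat$feature),
      loadings = loadings,
      singular_values = as.numeric(meta$singular_values),
      draws = dr, k = as.integer(meta$k), r = r,
      prior = as.numeric(meta$prior),
      mcmc = list(iterations = as.integer(meta$mcmc$iterations),
                  burn_in = as.integer(meta$mcmc$burn_in),
                  seed = as.integer(meta$mcmc$seed)),
      labels = as.list(meta$labels))
}
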