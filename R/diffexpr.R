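# Differential expression: pooled-variance Student t ranking,
# empirical-Bayes moderated t (unpaired and paired), Benjamini-Hochberg FDR
# adjustment and p-value histogram diagnostics.

#' Rank features by two-sample Student t
#'
#' Pooled-variance two-sample t per feature, contrast = mean(group 1) minus
#' mean(group 0). Rows are ordered by decreasing |t|, stable ties by input
#' order.
#'
#' @param se SummarizedExperiment or matrix.
#' @param y binary labels (0/1), one per sample.
#' @return data.frame: `feature`, `effect`, `t`, `df`, `p`, `q` (BH),
#'   ordered by decreasing `|t|`.
#' @export
studentTRank <- function(se, y) {
  m <- exprsMatrix(se)
  y <- as.integer(y)
  st <- .pooledT(m, y)
  ord <- order(-abs(st$t), seq_along(st$t))
  out <- data.frame(feature = rownames(m), effect = st$effect, t = st$t,
                    df = st$df, p = st$p, stringsAsFactors = FALSE)[ord, ]
  out$q <- bhAdjust(out$p)
  rownames(out) <- NULL
  out
}

# Vectorized pooled two-sample t over the rows of m. A singleton class is
# tolerated when min_per_class = 1 (its variance contributes zero weight),
# which leave-one-out folds on minimal cohorts rely on.
.pooledT <- function(m, y, min_per_class = 2L) {
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  n1 <- length(i1); n0 <- length(i0)
  if (n1 < min_per_class || n0 < min_per_class)
    stop("each class needs at least ", min_per_class,
         " samples (got ", n1, " and ", n0, ")")
  if (n1 + n0 < 3L) stop("need at least three samples in total")
  m1 <- rowMeans(m[, i1, drop = FALSE])
  m0 <- rowMeans(m[, i0, drop = FALSE])
  v1 <- if (n1 > 1L) apply(m[, i1, drop = FALSE], 1, var) else 0
  v0 <- if (n0 > 1L) apply(m[, i0, drop = FALSE], 1, var) else 0
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  sef <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / sef
  df <- n1 + n0 - 2
  list(effect = m1 - m0, t = t, df = rep(df, nrow(m)),
       p = 2 * pt(-abs(t), df), s2 = sp2, d = rep(df, nrow(m)),
       stdev_unscaled = rep(sqrt(1 / n1 + 1 / n0), nrow(m)))
}

# Newton solve of trigamma(x) = y (y > 0), as used for the prior df.
.trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

# Method-of-moments fit of the scaled inverse-chi-square prior on residual
# variances: matches mean and variance of log(s^2) through digamma/trigamma.
.fitVariancePrior <- function(s2, df) {
  ok <- s2 > 0
  if (!any(ok)) stop("all residual variances are zero; prior undefined")
  z <- log(s2[ok])
  dd <- df[ok]
  e <- z - digamma(dd / 2) + log(dd / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(dd / 2))
  if (is.na(evar) || evar <= 0) {
    # no detectable spread beyond chi-square sampling noise: infinite prior
    # df, pool to the mean variance
    list(d0 = Inf, s02 = mean(s2[ok]))
  } else {
    d0 <- 2 * .trigammaInverse(evar)
    list(d0 = d0, s02 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderated t-test
#'
#' Per-feature residual variances are shrunk toward a global prior variance
#' estimated by the method of moments on `log(s^2)` (digamma/trigamma
#' matching): `s_tilde^2 = (d0 s0^2 + d_g s_g^2) / (d0 + d_g)` and the
#' moderated t has `d0 + d_g` degrees of freedom. The unpaired design is a
#' two-group comparison; the paired design is a one-sample moderated t on
#' within-pair differences (condition 1 minus condition 0 per pair).
#' Features with zero residual variance are floored at the smallest positive
#' variance observed and flagged.
#'
#' @param se SummarizedExperiment or matrix.
#' @param group binary 0/1: class (unpaired) or within-pair condition
#'   (paired; e.g. 1 = lower lobe, 0 = upper lobe).
#' @param design `"unpaired"` or `"paired"`.
#' @param pairs pairing labels (e.g. patient IDs); required when paired.
#'   Every pair must be complete (one sample per condition).
#' @return data.frame in input feature order: `feature`, `effect`, `t`,
#'   `df`, `p`, `q`, `s2`, `zero_variance` flag; attributes `d0` and `s02`
#'   carry the prior.
#' @export
moderatedT <- function(se, group, design = c("unpaired", "paired"),
                       pairs = NULL) {
  design <- match.arg(design)
  m <- exprsMatrix(se)
  group <- as.integer(group)
  if (design == "unpaired") {
    st <- .pooledT(m, group)
    eff <- st$effect; s2 <- st$s2; dg <- st$d; c_se <- st$stdev_unscaled
  } else {
    if (is.null(pairs)) stop("paired design requires pairs")
    pairs <- as.character(pairs)
    ids <- unique(pairs)
    i1 <- i0 <- integer(length(ids))
    for (j in seq_along(ids)) {
      idx <- which(pairs == ids[j])
      if (length(idx) != 2L || sum(group[idx]) != 1L)
        stop("incomplete pair: ", ids[j])
      i1[j] <- idx[group[idx] == 1L]
      i0[j] <- idx[group[idx] == 0L]
    }
    np <- length(ids)
    if (np < 2L) stop("need at least two complete pairs")
    d <- m[, i1, drop = FALSE] - m[, i0, drop = FALSE]
    eff <- rowMeans(d)
    s2 <- apply(d, 1, var)
    dg <- rep(np - 1, nrow(m))
    c_se <- rep(sqrt(1 / np), nrow(m))
  }
  zero <- s2 == 0
  if (all(zero)) stop("all residual variances are zero; prior undefined")
  if (any(zero)) s2[zero] <- min(s2[!zero])
  prior <- .fitVariancePrior(s2, dg)
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s02, length(s2))
             else (prior$d0 * prior$s02 + dg * s2) / (prior$d0 + dg)
  t <- eff / (sqrt(s2_post) * c_se)
  # total df capped at the pooled residual df across all features
  df <- pmin(prior$d0 + dg, sum(dg))
  p <- 2 * pt(-abs(t), df)
  out <- data.frame(feature = rownames(m), effect = eff, t = t, df = df,
                    p = p, q = bhAdjust(p), s2 = s2,
                    zero_variance = zero, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "d0") <- prior$d0
  attr(out, "s02") <- prior$s02
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH: `q_(i) = min_{j >= i} (n/j) p_(j)`, capped at 1,
#' returned in the input order.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted q-values.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' P-value histogram with excess-over-uniform estimate
#'
#' Counts per bin of width `bin_width` on \[0, 1\] (left-closed bins, 1
#' falls in the last bin) and the excess of the first bin over the uniform
#' expectation: `(count in [0, 0.05) - n * 0.05) / n` for the default width.
#'
#' @param p p-values.
#' @param bin_width bin width (default 0.05).
#' @return list: `breaks`, `counts`, `excess`.
#' @export
pvalueHistogram <- function(p, bin_width = 0.05) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  breaks <- unique(c(seq(0, 1, by = bin_width), 1))
  cuts <- findInterval(p, breaks, rightmost.closed = TRUE)
  counts <- tabulate(cuts, nbins = length(breaks) - 1L)
  first <- sum(p < breaks[2L])
  list(breaks = breaks, counts = counts,
       excess = (first - length(p) * breaks[2L]) / length(p))
}
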