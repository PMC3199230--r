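# Diagnostic evaluation: ROC/AUC, Youden cutoff, confusion metrics and the
# Wilcoxon rank-sum association test.

#' ROC curve and Mann-Whitney AUC
#'
#' Sweeps the unique probability values as cutoffs (predicting positive when
#' `prob >= cutoff`) and computes the AUC as the Mann-Whitney concordance
#' probability with ties counted 1/2.
#'
#' @param probs per-sample predicted probabilities (or any score).
#' @param labels binary 0/1 truth.
#' @return list: `roc` (data.frame cutoff, sensitivity, specificity) and
#'   `auc`.
#' @export
rocCurve <- function(probs, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  cuts <- sort(unique(probs), decreasing = TRUE)
  sens <- vapply(cuts, function(c) sum(probs >= c & labels == 1L) / n1,
                 numeric(1))
  spec <- vapply(cuts, function(c) sum(probs < c & labels == 0L) / n0,
                 numeric(1))
  rk <- rank(probs)   # midranks handle ties at 1/2
  auc <- (sum(rk[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(roc = data.frame(cutoff = cuts, sensitivity = sens,
                        specificity = spec),
       auc = auc)
}

#' Youden-index operating point
#'
#' `J = max(sensitivity + specificity - 1)` over the swept cutoffs; ties
#' break toward the smallest cutoff (higher sensitivity).
#'
#' @param roc result of [rocCurve()] (or its `roc` data.frame).
#' @return list: `cutoff`, `J`.
#' @export
youdenCutoff <- function(roc) {
  df <- if (is.data.frame(roc)) roc else roc$roc
  j <- df$sensitivity + df$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(df$cutoff[best])]
  list(cutoff = df$cutoff[pick], J = j[pick])
}

#' Confusion metrics at a fixed cutoff
#'
#' Predicts positive when `prob >= cutoff` and reports the 2x2 counts with
#' sensitivity, specificity, positive/negative predictive values and
#' overall accuracy. PPV (NPV) is `NA` when no sample is predicted
#' positive (negative).
#'
#' @param probs probabilities.
#' @param labels binary 0/1 truth.
#' @param cutoff decision threshold in \[0, 1\].
#' @return list of counts (`tp`, `fp`, `tn`, `fn`) and rates
#'   (`sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`).
#' @export
confusionMetrics <- function(probs, labels, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  labels <- as.integer(labels)
  pred <- probs >= cutoff
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       ppv = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
       npv = if (tn + fn == 0L) NA_real_ else tn / (tn + fn),
       accuracy = (tp + tn) / length(labels))
}

#' Wilcoxon rank-sum association test
#'
#' Two-sided test of a location difference between case and control
#' predicted probabilities: exact permutation null when the combined sample
#' size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param probs_case,probs_control nonempty numeric vectors.
#' @return list: `U` (Mann-Whitney statistic of cases over controls),
#'   `p_value`.
#' @export
wilcoxonRankSum <- function(probs_case, probs_control) {
  if (!length(probs_case) || !length(probs_control))
    stop("both groups must be nonempty")
  n <- length(probs_case) + length(probs_control)
  ties <- anyDuplicated(c(probs_case, probs_control)) > 0L
  wt <- suppressWarnings(
    wilcox.test(probs_case, probs_control,
                exact = (n <= 20L && !ties), correct = TRUE,
                alternative = "two.sided"))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Full diagnostic evaluation of predicted probabilities
#'
#' Assembles a [ValidationReport-class]: ROC/AUC, the Youden cutoff (or a
#' supplied one), confusion metrics at that cutoff, and the Wilcoxon
#' rank-sum test.
#'
#' @param probs named per-sample probabilities.
#' @param labels binary 0/1 truth, same order.
#' @param cutoff `"youden"` (default) or a numeric threshold.
#' @return a [ValidationReport-class].
#' @export
validationReport <- function(probs, labels, cutoff = "youden") {
  labels <- as.integer(labels)
  rc <- rocCurve(probs, labels)
  yj <- youdenCutoff(rc)
  cut <- if (identical(cutoff, "youden")) yj$cutoff else as.numeric(cutoff)
  cm <- confusionMetrics(probs, labels, cut)
  wx <- wilcoxonRankSum(probs[labels == 1L], probs[labels == 0L])
  nm <- names(probs) %||% as.character(seq_along(probs))
  new("ValidationReport",
      probabilities = setNames(as.numeric(probs), nm),
      labels = setNames(labels, nm), roc = rc$roc, auc = rc$auc,
      youden = yj, confusion = cm, wilcoxon = wx)
}
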