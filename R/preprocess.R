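# Feature filtering, coefficient-of-variation selection, and collapsing of
# lobe pairs to one sample per patient.

#' Filter to annotated, expressed features
#'
#' Retains features that carry at least one gene identifier AND whose mean
#' log2 expression across all samples is strictly greater than `min_mean`.
#' Feature order is preserved.
#'
#' @param se SummarizedExperiment with gene annotation in `rowData`.
#' @param min_mean expression threshold on the log2 scale (default 4).
#' @return list: `se` (filtered) and `report` (counts: `n_input`,
#'   `n_dropped_unannotated`, `n_dropped_low_expression`, `n_retained`).
#' @export
filterFeatures <- function(se, min_mean = 4.0) {
  m <- exprsMatrix(se)
  ann <- annotationList(se)
  annotated <- lengths(ann) > 0L
  mu <- rowMeans(m)
  keep <- annotated & mu > min_mean
  report <- list(n_input = nrow(m),
                 n_dropped_unannotated = sum(!annotated),
                 n_dropped_low_expression = sum(annotated & mu <= min_mean),
                 n_retained = sum(keep))
  if (!any(keep))
    stop("no features pass the filter; review min_mean = ", min_mean,
         " against the data's expression scale")
  list(se = se[keep, ], report = report)
}

#' Select the most variable features by coefficient of variation
#'
#' Keeps the `ceiling(fraction * n)` features with the largest CoV = sd/mean
#' (sample SD, computed on the log2 values). Ties break stably by input
#' order; output preserves input feature order.
#'
#' @param se SummarizedExperiment.
#' @param fraction fraction of features to keep, in (0, 1].
#' @return the subsetted SummarizedExperiment.
#' @export
selectTopCoV <- function(se, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  m <- exprsMatrix(se)
  mu <- rowMeans(m)
  if (any(mu <= 0))
    stop("coefficient of variation undefined: feature ",
         rownames(m)[mu <= 0][1L], " has non-positive mean")
  cov <- apply(m, 1, sd) / mu
  n_keep <- ceiling(fraction * nrow(m))
  ord <- order(-cov, seq_along(cov))   # stable: ties by input order
  keep <- sort(ord[seq_len(n_keep)])
  se[keep, ]
}

#' Collapse lobe pairs to one sample per patient
#'
#' Keeps exactly one sample per `patient_id`: the preferred lobe when
#' present, otherwise the patient's single available sample. Two samples of
#' the same patient and lobe are ambiguous and raise an error.
#'
#' @param se SummarizedExperiment with `patient_id` and `lobe` in `colData`.
#' @param prefer lobe kept when a patient has a pair (default `"upper"`).
#' @return the subsetted SummarizedExperiment (one column per patient).
#' @export
collapseLobePairs <- function(se, prefer = c("upper", "lower")) {
  prefer <- match.arg(prefer)
  ph <- phenoFrame(se)
  if (!all(c("patient_id", "lobe") %in% names(ph)))
    stop("colData must provide patient_id and lobe")
  other <- setdiff(c("upper", "lower"), prefer)
  priority <- setNames(c(1L, 2L, 3L), c(prefer, other, "unknown"))
  keep <- logical(ncol(se))
  for (pid in unique(ph$patient_id)) {
    idx <- which(ph$patient_id == pid)
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    lb <- ph$lobe[idx]
    if (anyDuplicated(lb))
      stop("patient ", pid, " has multiple samples from the same lobe (",
           lb[duplicated(lb)][1L], "): ambiguous collapse")
    keep[idx[which.min(priority[lb])]] <- TRUE
  }
  se[, keep]
}
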