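# Cross-platform signature transfer: many-by-many feature mapping through
# shared gene identifiers, aggregation into training-feature space,
# per-feature scale/shift normalization to the training moments, and
# least-squares projection through training-only SVD loadings.

#' Derive a many-by-many feature mapping from gene annotations
#'
#' Links every (training feature, validation feature) pair sharing at least
#' one gene identifier. Either side may repeat (many-by-many).
#'
#' @param annotation_train,annotation_val named lists of character vectors
#'   (feature ID -> gene IDs), e.g. from [annotation()] on two platforms.
#' @return data.frame `train_id`, `val_id` (no duplicate links; possibly
#'   zero rows).
#' @export
deriveMapping <- function(annotation_train, annotation_val) {
  if (!length(annotation_train) || !length(annotation_val))
    stop("both annotations must be nonempty")
  flat <- function(ann) {
    n <- lengths(ann)
    data.frame(feature = rep(names(ann), n),
               gene = unlist(ann, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  a <- flat(annotation_train)
  b <- flat(annotation_val)
  mg <- merge(a, b, by = "gene", suffixes = c("_train", "_val"))
  out <- unique(data.frame(train_id = mg$feature_train,
                           val_id = mg$feature_val,
                           stringsAsFactors = FALSE))
  out[order(out$train_id, out$val_id), , drop = FALSE]
}

#' Gene annotation of a cohort container
#'
#' @param se SummarizedExperiment with `gene_ids` in `rowData`.
#' @return named list of character vectors.
#' @export
annotation <- function(se) annotationList(se)

#' Map validation expression into training-feature space
#'
#' For each signature feature, the mapped value is the unweighted mean (or
#' median) over all linked validation features; signature features with no
#' link are recorded as unmapped and excluded.
#'
#' @param se_val validation SummarizedExperiment or matrix.
#' @param mapping data.frame `train_id`, `val_id` (see [deriveMapping()]).
#' @param signature_features training feature IDs to reconstruct.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return list: `exprs` (matrix, mapped signature features x samples) and
#'   `report` (`n_signature_features`, `n_mapped`, `coverage`, `unmapped`).
#' @export
mapExpression <- function(se_val, mapping, signature_features,
                          aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  m <- exprsMatrix(se_val)
  mapping <- mapping[mapping$train_id %in% signature_features &
                     mapping$val_id %in% rownames(m), , drop = FALSE]
  linked <- split(mapping$val_id, mapping$train_id)
  mapped <- intersect(signature_features, names(linked))
  if (!length(mapped))
    stop("zero mapping coverage on the signature features")
  agg <- if (aggregate == "mean") colMeans
         else function(x) apply(x, 2, stats::median)
  out <- t(vapply(mapped, function(f) {
    rows <- m[linked[[f]], , drop = FALSE]
    if (nrow(rows) == 1L) rows[1L, ] else agg(rows)
  }, numeric(ncol(m))))
  dimnames(out) <- list(mapped, colnames(m))
  report <- list(n_signature_features = length(signature_features),
                 n_mapped = length(mapped),
                 coverage = length(mapped) / length(signature_features),
                 unmapped = setdiff(signature_features, mapped))
  list(exprs = out, report = report)
}

#' Scale/shift normalize validation features to training moments
#'
#' Per feature: z-score with the validation cohort's own mean/SD, then
#' rescale to the training feature's mean/SD, so the first two moments match
#' the training data exactly. Features with zero validation variance are
#' dropped with a warning. A global variant (single cohort-wide scale and
#' shift) is available.
#'
#' @param x matrix in training-feature space (e.g. from [mapExpression()]).
#' @param center,scale named training per-feature mean and SD (covering the
#'   rows of `x`).
#' @param method `"per_feature"` (default) or `"global"`.
#' @return normalized matrix; attribute `dropped` lists removed features.
#' @export
scaleShiftNormalize <- function(x, center, scale,
                                method = c("per_feature", "global")) {
  method <- match.arg(method)
  feats <- rownames(x)
  center <- center[feats]
  scale <- scale[feats]
  if (any(is.na(center)) || any(is.na(scale)))
    stop("training stats missing for some features")
  if (method == "global") {
    v_mu <- mean(x); v_sd <- sd(as.numeric(x))
    out <- (x - v_mu) / v_sd * mean(scale) + mean(center)
    attr(out, "dropped") <- character(0)
    return(out)
  }
  v_mu <- rowMeans(x)
  v_sd <- apply(x, 1, sd)
  zero <- v_sd == 0
  if (any(zero)) {
    warning("dropping zero-variance validation features: ",
            paste(utils::head(feats[zero], 5L), collapse = ", "))
  }
  keep <- !zero
  out <- (x[keep, , drop = FALSE] - v_mu[keep]) / v_sd[keep] *
    scale[keep] + center[keep]
  attr(out, "dropped") <- feats[zero]
  out
}

#' Project normalized validation data through a trained signature
#'
#' Standardizes with the training center/scale, projects into factor space
#' by least squares on the available loading rows (the pseudo-inverse of the
#' loading submatrix, rescaled by the inverse singular values; exact when
#' all features are present), and computes predicted probabilities from the
#' stored posterior draws.
#'
#' @param model a [SignatureModel-class].
#' @param x normalized matrix in training-feature space (a subset of the
#'   model's features is allowed, but at least `r` rows are required).
#' @param type probability type, see [predictProbability()].
#' @return list: `scores` (samples x r), `probabilities` (named numeric).
#' @export
projectValidation <- function(model, x,
                              type = c("posterior_mean_prob",
                                       "prob_at_mean")) {
  type <- match.arg(type)
  avail <- intersect(model@features, rownames(x))
  if (length(avail) < model@r)
    stop("fewer mapped features (", length(avail), ") than factors (",
         model@r, ")")
  xs <- (x[avail, , drop = FALSE] - model@center[avail]) /
    model@scale[avail]
  idx <- match(avail, model@features)
  f <- .projectScores(xs, model@loadings[idx, , drop = FALSE],
                      model@singular_values)
  rownames(f) <- colnames(x)
  list(scores = f, probabilities = .drawProbabilities(model@draws, f, type))
}
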