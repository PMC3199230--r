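# Internal helpers shared across the package.

#' @importFrom methods new validObject is slot
#' @importFrom stats cor pf pnorm pt qnorm rnorm runif sd var prcomp
#'   p.adjust wilcox.test setNames aggregate
#' @importFrom utils read.delim write.table head packageVersion
NULL

# Derive a reproducible sub-seed from a base seed and a stream name, so that
# independent stages (baseline draws, design, noise, per-fold fits) consume
# independent streams and adding features to one stage does not perturb the
# others. Result is kept strictly inside the 32-bit signed integer range.
substreamSeed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483563
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483563 + 1)
}

# Run an expression under a local RNG state (restores .Random.seed after).
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Extract the log2 expression matrix from a SummarizedExperiment (assay
# "exprs" if present, else the first assay) or pass a plain matrix through.
exprsMatrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x)))
      stop("expression matrix must have feature rownames and sample colnames")
    return(x)
  }
  if (methods::is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    a <- if (!is.null(nm) && "exprs" %in% nm)
      SummarizedExperiment::assay(x, "exprs")
    else SummarizedExperiment::assay(x, 1)
    return(a)
  }
  stop("expected a SummarizedExperiment or a named matrix")
}

# Gene annotation as a plain named list of character vectors (possibly empty),
# one entry per feature.
annotationList <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    rd <- SummarizedExperiment::rowData(x)
    if ("gene_ids" %in% colnames(rd)) {
      out <- as.list(rd$gene_ids)
      names(out) <- rownames(x)
      return(lapply(out, as.character))
    }
    out <- rep(list(character(0)), nrow(x))
    names(out) <- rownames(x)
    return(out)
  }
  stop("expected a SummarizedExperiment")
}

phenoFrame <- function(x) {
  if (!methods::is(x, "SummarizedExperiment"))
    stop("expected a SummarizedExperiment")
  as.data.frame(SummarizedExperiment::colData(x))
}

# Validity checks on the cohort container (unique finite log2 matrix with
# unique IDs); used by readers, the simulator and downstream entry points.
validateExpression <- function(x) {
  m <- exprsMatrix(x)
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature ID: ",
         rownames(m)[duplicated(rownames(m))][1L])
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample ID: ", colnames(m)[duplicated(colnames(m))][1L])
  if (!all(is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at feature ", rownames(m)[idx[1L]],
         ", sample ", colnames(m)[idx[2L]])
  }
  invisible(TRUE)
}
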