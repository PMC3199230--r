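# Unsupervised structure analysis: Pearson-distance UPGMA clustering, PCA
# with variance accounting, matched/unmatched sample correlations, and
# one-way intraclass correlation for lobe pairs.

#' Pearson-correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the Pearson correlation of two sample
#' columns across features; symmetric, zero diagonal.
#'
#' @param se SummarizedExperiment or named matrix (features x samples).
#' @return symmetric numeric matrix with sample dimnames.
#' @export
pearsonDistance <- function(se) {
  m <- exprsMatrix(se)
  if (ncol(m) < 2L) stop("need at least two samples")
  v <- apply(m, 2, var)
  if (any(v == 0))
    stop("zero-variance sample: ", colnames(m)[v == 0][1L])
  d <- 1 - cor(m)
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates with unweighted average linkage: the distance between two
#' clusters is the mean over all cross-pair distances. When several pairs
#' tie at the minimum, the pair whose (sorted) representative labels are
#' lexicographically smallest merges first, making the dendrogram fully
#' deterministic. Returns a standard `hclust` object (merge matrix, heights,
#' plotting order, labels).
#'
#' @param D symmetric distance matrix (zero diagonal).
#' @param labels leaf labels; defaults to `rownames(D)`.
#' @return an object of class `hclust` with `method = "average"`.
#' @export
averageLinkage <- function(D, labels = rownames(D)) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (ncol(D) != n || max(abs(D - t(D))) > 1e-10)
    stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have a zero diagonal")
  # active clusters: id (negative leaf / positive merge row), members,
  # representative label = lexicographically smallest member label
  clus <- lapply(seq_len(n), function(i)
    list(id = -i, members = i, rep = labels[i]))
  dist_between <- function(a, b)
    mean(D[a$members, b$members])
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_len(length(clus) - 1L)) for (j in (i + 1L):length(clus)) {
      d <- dist_between(clus[[i]], clus[[j]])
      pair_rep <- sort(c(clus[[i]]$rep, clus[[j]]$rep))
      if (is.null(best) || d < best$d - 1e-12 ||
          (abs(d - best$d) <= 1e-12 &&
           (pair_rep[1L] < best$rep[1L] ||
            (pair_rep[1L] == best$rep[1L] && pair_rep[2L] < best$rep[2L])))) {
        best <- list(i = i, j = j, d = d, rep = pair_rep)
      }
    }
    a <- clus[[best$i]]; b <- clus[[best$j]]
    merge[step, ] <- sort(c(a$id, b$id))
    height[step] <- best$d
    clus[[best$i]] <- list(id = step, members = c(a$members, b$members),
                           rep = min(a$rep, b$rep))
    clus[[best$j]] <- NULL
  }
  # leaf order by traversal of the merge tree
  orderOf <- function(node) {
    if (node < 0L) return(-node)
    c(orderOf(merge[node, 1L]), orderOf(merge[node, 2L]))
  }
  structure(list(merge = merge, height = height,
                 order = orderOf(n - 1L), labels = labels,
                 method = "average", dist.method = "pearson",
                 call = match.call()),
            class = "hclust")
}

#' Export a dendrogram as Newick
#'
#' Converts an `hclust` tree to `ape::phylo` (branch lengths are differences
#' of merge heights) and writes Newick text.
#'
#' @param hc an `hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Principal component analysis of samples
#'
#' SVD of the feature-centered data: per-feature means are removed, samples
#' are projected on the right singular vectors. Variance explained per
#' component is the squared singular value over their total.
#'
#' @param se SummarizedExperiment or matrix (features x samples).
#' @param n_components number of components to return.
#' @param scale. also scale features to unit variance (default FALSE).
#' @return list: `loadings` (features x r), `scores` (samples x r),
#'   `variance_explained` (over all components, truncated to r for scores).
#' @export
expressionPCA <- function(se, n_components = 2L, scale. = FALSE) {
  m <- exprsMatrix(se)
  r_max <- min(nrow(m), ncol(m) - 1L)
  if (n_components > r_max)
    stop("n_components must be at most min(features, samples - 1) = ", r_max)
  pc <- prcomp(t(m), center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       scores = pc$x[, seq_len(n_components), drop = FALSE],
       variance_explained = ve,
       center = pc$center)
}

#' Matched versus unmatched sample correlations
#'
#' Mean Pearson correlation over same-patient lobe pairs, against the mean
#' over all distinct-patient case-sample pairs.
#'
#' @param se SummarizedExperiment with `phenotype` and `patient_id` in
#'   `colData`.
#' @return list: `matched`, `unmatched`, `n_pairs`.
#' @export
pairedCorrelation <- function(se) {
  ph <- phenoFrame(se)
  cases <- which(ph$phenotype == 1L)
  if (length(cases) < 2L) stop("need at least two case samples")
  m <- exprsMatrix(se)[, cases, drop = FALSE]
  pid <- ph$patient_id[cases]
  r <- cor(m)
  same <- outer(pid, pid, "==") & upper.tri(r)
  diff <- (!outer(pid, pid, "==")) & upper.tri(r)
  if (!any(same)) stop("no same-patient lobe pairs present")
  list(matched = mean(r[same]), unmatched = mean(r[diff]),
       n_pairs = sum(same))
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' For balanced groups of size k: `ICC = (MSB - MSW) / (MSB + (k-1) MSW)`
#' with the p-value from `F = MSB/MSW` on `(n_groups - 1, n_groups (k - 1))`
#' degrees of freedom.
#'
#' @param values numeric, one scalar per sample (e.g. PC1 scores).
#' @param groups grouping labels (e.g. patient IDs); must be balanced with
#'   at least two groups of at least two members each.
#' @return list: `icc`, `f_statistic`, `p_value`, `msb`, `msw`.
#' @export
iccOneWay <- function(values, groups) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least two groups")
  if (length(unique(as.integer(sizes))) != 1L || any(sizes < 2L))
    stop("groups must be balanced with at least two members each")
  k <- as.integer(sizes[1L])
  g <- length(sizes)
  grand <- mean(values)
  gm <- tapply(values, groups, mean)
  ssb <- k * sum((gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  msb <- ssb / (g - 1)
  msw <- ssw / (g * (k - 1))
  f <- msb / msw
  p <- pf(f, g - 1, g * (k - 1), lower.tail = FALSE)
  list(icc = (msb - msw) / (msb + (k - 1) * msw),
       f_statistic = f, p_value = p, msb = msb, msw = msw)
}
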