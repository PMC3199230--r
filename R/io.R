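# Tabular I/O for expression matrices and phenotype tables, plus cohort
# summary statistics. All files are UTF-8, tab-delimited, '.' decimal.

#' Assemble a cohort SummarizedExperiment
#'
#' Combines a log2 expression matrix, an optional feature -> gene annotation
#' map and an optional phenotype table into the container used throughout
#' the package.
#'
#' @param exprs numeric matrix, features x samples, with rownames and
#'   colnames.
#' @param annotation named list (feature ID -> character vector of gene
#'   IDs), or `NULL` for no annotation.
#' @param pheno data.frame of per-sample metadata with a `sample_id`
#'   column (or rownames) covering all samples, or `NULL`.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`, `rowData(x)$gene_ids` as a CharacterList and phenotype
#'   columns in `colData`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' cohortExperiment(m, annotation = list(g1 = "GENEA", g2 = character(0)))
#' @export
cohortExperiment <- function(exprs, annotation = NULL, pheno = NULL) {
  if (anyDuplicated(rownames(exprs)))
    stop("duplicate feature ID: ",
         rownames(exprs)[duplicated(rownames(exprs))][1L])
  if (anyDuplicated(colnames(exprs)))
    stop("duplicate sample ID: ",
         colnames(exprs)[duplicated(colnames(exprs))][1L])
  gene_ids <- rep(list(character(0)), nrow(exprs))
  names(gene_ids) <- rownames(exprs)
  if (!is.null(annotation)) {
    keep <- intersect(names(annotation), rownames(exprs))
    gene_ids[keep] <- lapply(annotation[keep], as.character)
  }
  rd <- S4Vectors::DataFrame(gene_ids = IRanges::CharacterList(gene_ids))
  rownames(rd) <- rownames(exprs)
  cd <- S4Vectors::DataFrame(row.names = colnames(exprs))
  if (!is.null(pheno)) {
    pheno <- as.data.frame(pheno)
    ids <- if ("sample_id" %in% names(pheno)) pheno$sample_id
           else rownames(pheno)
    miss <- setdiff(colnames(exprs), ids)
    if (length(miss))
      stop("phenotype table lacks samples: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    pheno <- pheno[match(colnames(exprs), ids), , drop = FALSE]
    rownames(pheno) <- colnames(exprs)
    cd <- S4Vectors::DataFrame(pheno)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), rowData = rd, colData = cd)
  validateExpression(se)
  se
}

#' Read a tab-separated log2 expression matrix
#'
#' Expects a header row of sample IDs and a first column of feature IDs.
#' An optional two-column annotation file (`feature_id`, `gene_id`; multiple
#' lines per feature allowed) populates the gene annotation.
#'
#' @param path TSV expression file.
#' @param annotation_path optional TSV annotation file.
#' @return a SummarizedExperiment (see [cohortExperiment()]).
#' @export
readExpressionMatrix <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L)
    stop("empty expression file: ", path)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", quote = "")
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("malformed expression file (empty or no samples): ", path)
  feat <- raw[[1L]]
  if (anyDuplicated(feat))
    stop("duplicate feature ID: ", feat[duplicated(feat)][1L])
  samp <- colnames(raw)[-1L]
  if (anyDuplicated(samp))
    stop("duplicate sample ID: ", samp[duplicated(samp)][1L])
  m <- matrix(NA_real_, nrow(raw), length(samp),
              dimnames = list(feat, samp))
  for (j in seq_along(samp)) {
    col <- raw[[j + 1L]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric expression value at feature ", feat[bad[1L]],
           ", sample ", samp[j], ": '", col[bad[1L]], "'")
    m[, j] <- v
  }
  ann <- NULL
  if (!is.null(annotation_path)) ann <- readAnnotation(annotation_path)
  cohortExperiment(m, annotation = ann)
}

#' Read a feature annotation file
#'
#' @param path TSV with columns `feature_id`, `gene_id` (one pair per line).
#' @return named list of character vectors.
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "")
  if (!all(c("feature_id", "gene_id") %in% names(tab)))
    stop("annotation file needs columns feature_id and gene_id: ", path)
  split(tab$gene_id, factor(tab$feature_id, levels = unique(tab$feature_id)))
}

#' Write an expression matrix (and optional annotation) as TSV
#'
#' Values are written with 17 significant digits so a read/write round trip
#' preserves them bit-for-bit.
#'
#' @param x SummarizedExperiment or named matrix.
#' @param path output TSV path.
#' @param annotation_path optional path for the annotation table.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, annotation_path = NULL) {
  m <- exprsMatrix(x)
  df <- data.frame(feature_id = rownames(m),
                   apply(m, 2, function(v) sprintf("%.17g", v)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", colnames(m))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation_path) &&
      methods::is(x, "SummarizedExperiment")) {
    ann <- annotationList(x)
    n <- lengths(ann)
    tab <- data.frame(feature_id = rep(names(ann), n),
                      gene_id = unlist(ann, use.names = FALSE))
    write.table(tab, annotation_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

.lobe_levels <- c("upper", "lower", "unknown")
.type_levels <- c("biopsy", "explant", "control")

#' Read a phenotype table
#'
#' Tab-separated with columns `sample_id`, `phenotype`, `patient_id`,
#' `lobe`, `sample_type`, plus free covariate columns. Phenotype labels are
#' mapped to 0/1 through configurable synonym lists; unknown lobe tokens map
#' to `"unknown"`. Empty cells and `"NA"` are read as missing.
#'
#' @param path TSV file.
#' @param case_labels,control_labels label synonyms mapped to 1 and 0.
#' @return data.frame with validated `phenotype` (integer 0/1), `lobe` and
#'   `sample_type` columns and covariates coerced to numeric where possible.
#' @export
readPhenotypeTable <- function(path,
                               case_labels = c("1", "IPF", "case"),
                               control_labels = c("0", "Normal", "control")) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", na.strings = c("", "NA"))
  need <- c("sample_id", "phenotype", "patient_id", "lobe", "sample_type")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  if (any(is.na(tab$sample_id)))
    stop("missing sample_id at row ", which(is.na(tab$sample_id))[1L])
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample ID: ",
         tab$sample_id[duplicated(tab$sample_id)][1L])
  y <- ifelse(tab$phenotype %in% case_labels, 1L,
              ifelse(tab$phenotype %in% control_labels, 0L, NA_integer_))
  if (any(is.na(y)))
    stop("phenotype label outside {0,1} and configured synonyms: '",
         tab$phenotype[is.na(y)][1L], "'")
  lobe <- tolower(tab$lobe)
  lobe[!(lobe %in% .lobe_levels) | is.na(lobe)] <- "unknown"
  st <- tolower(tab$sample_type)
  if (any(!st %in% .type_levels, na.rm = TRUE) || any(is.na(st)))
    stop("sample_type must be one of ",
         paste(.type_levels, collapse = "/"))
  out <- data.frame(sample_id = tab$sample_id, phenotype = y,
                    patient_id = tab$patient_id, lobe = lobe,
                    sample_type = st, stringsAsFactors = FALSE)
  for (cv in setdiff(names(tab), need)) {
    v <- tab[[cv]]
    num <- suppressWarnings(as.numeric(v))
    out[[cv]] <- if (all(is.na(num) == is.na(v))) num else v
  }
  rownames(out) <- out$sample_id
  out
}

#' Write a phenotype table as TSV
#'
#' @param pheno data.frame as returned by [readPhenotypeTable()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypeTable <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach a phenotype table to an expression container
#'
#' @param se SummarizedExperiment.
#' @param pheno data.frame with `sample_id` covering all samples of `se`.
#' @return `se` with phenotype columns in `colData`.
#' @export
attachPhenotype <- function(se, pheno) {
  cohortExperiment(exprsMatrix(se), annotation = annotationList(se),
                   pheno = pheno)
}

#' Cohort summary statistics
#'
#' Per-group summaries in the style of a clinical Table 1: for numeric
#' covariates the per-group n, mean and standard error (sample SD with
#' n-1 denominator over sqrt(n)); for categorical covariates the per-level
#' count and half-up-rounded percentage. Each patient is counted once
#' (deduplicated by `patient_id`, keeping the first row).
#'
#' @param pheno phenotype data.frame.
#' @param group_field column defining the groups (e.g. `sample_type`).
#' @param fields covariate columns to summarize.
#' @return list with one element per group; each group holds `n_patients`
#'   plus, per covariate, either `(n, mean, se)` or a per-level table of
#'   `(n, percent)`. SE is `NA` when fewer than 2 non-missing values.
#' @examples
#' path <- system.file("extdata", "table1_cohort.tsv", package = "bprsig")
#' ph <- readPhenotypeTable(path)
#' cases <- ph[ph$phenotype == 1, ]
#' s <- summarizeCohort(cases, "sample_type", c("age", "sex"))
#' s$biopsy$age$mean
#' @export
summarizeCohort <- function(pheno, group_field, fields) {
  if (!group_field %in% names(pheno))
    stop("unknown group field: ", group_field)
  bad <- setdiff(fields, names(pheno))
  if (length(bad)) stop("unknown covariate field: ", bad[1L])
  dedup <- pheno[!duplicated(pheno$patient_id), , drop = FALSE]
  groups <- unique(dedup[[group_field]])
  out <- list()
  for (g in groups) {
    sub <- dedup[dedup[[group_field]] == g, , drop = FALSE]
    entry <- list(n_patients = nrow(sub))
    for (f in fields) {
      v <- sub[[f]]
      if (is.numeric(v)) {
        v <- v[!is.na(v)]
        n <- length(v)
        entry[[f]] <- list(
          n = n,
          mean = if (n > 0L) mean(v) else NA_real_,
          se = if (n >= 2L) stats::sd(v) / sqrt(n) else NA_real_)
      } else {
        v <- v[!is.na(v)]
        lev <- unique(v)
        entry[[f]] <- lapply(setNames(lev, lev), function(l) {
          n_l <- sum(v == l)
          # round half up, so 5/6 -> 83%
          list(n = n_l, percent = floor(100 * n_l / length(v) + 0.5))
        })
      }
    }
    out[[as.character(g)]] <- entry
  }
  out
}
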