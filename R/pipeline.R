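# End-to-end orchestration: schema-validated configuration and the scripted
# synthetic workflow (simulate -> preprocess -> explore -> differential
# expression -> tune -> train -> cross-platform transfer -> validate), with
# a machine-readable manifest so any run is exactly reproducible.

.configTemplate <- function() {
  list(
    seed = 1L,
    simulate = list(
      train = list(n_features = 1L, frac_annotated = 1, n_cases = 1L,
                   n_controls = 1L, frac_paired_lobes = 1, frac_explant = 1,
                   n_diff = 1L, n_batch = 1L, effect_size = 1,
                   batch_effect = 1, within_patient_rho = 1,
                   baseline_mean = 1, baseline_sd = 1, noise_sd = 1),
      validation = list(n_cases = 1L, n_controls = 1L,
                        frac_paired_lobes = 1, frac_explant = 1),
      platform2 = list(frac_one_to_one = 1, frac_many_to_one = 1,
                       frac_one_to_many = 1, drop_frac = 1,
                       scale_sd = 1, shift_sd = 1, noise_sd = 1)),
    input = list(expression_path = "", annotation_path = "",
                 phenotype_path = ""),
    preprocess = list(min_mean = 1, cov_fraction = 1, prefer_lobe = ""),
    model = list(contrast = "", grid = 1L, r = 1L, prior = 1,
                 mcmc_loo = list(iterations = 1L, burn_in = 1L),
                 mcmc_final = list(iterations = 1L, burn_in = 1L)),
    validate = list(cutoff = ""))
}

.checkKeys <- function(x, template, path = "config") {
  unknown <- setdiff(names(x), names(template))
  if (length(unknown))
    stop("unknown ", path, " key: ", unknown[1L])
  for (nm in names(x)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(x[[nm]]))
      .checkKeys(x[[nm]], template[[nm]], paste0(path, "$", nm))
  }
  invisible(TRUE)
}

#' Validate a pipeline configuration
#'
#' Checks the key schema (unknown keys rejected), the presence of explicit
#' seeds/MCMC settings, and that any declared input files exist.
#'
#' @param config a pipeline configuration list (see [makeDemoConfig()]).
#' @return the config, invisibly; errors otherwise.
#' @export
validatePipelineConfig <- function(config) {
  .checkKeys(config, .configTemplate())
  if (is.null(config$seed)) stop("config must carry an explicit seed")
  for (blk in c("mcmc_loo", "mcmc_final")) {
    mc <- config$model[[blk]]
    if (is.null(mc$iterations) || is.null(mc$burn_in))
      stop("config$model$", blk, " must set iterations and burn_in")
  }
  for (p in unlist(config$input)) {
    if (!is.null(p) && nzchar(p) && !file.exists(p))
      stop("input file not found: ", p)
  }
  if (!is.null(config$model$contrast) &&
      !config$model$contrast %in% c("all", "biopsy", "explant"))
    stop("model$contrast must be one of all/biopsy/explant")
  invisible(config)
}

#' Demo pipeline configurations
#'
#' `"tiny"` is a minutes-scale smoke configuration (2,000 features, model
#' grid 20/40/60, short MCMC chains). `"paper_shape"` mirrors the emulated
#' study: 11 case + 6 control training patients, a 31 case / 15 control
#' validation cohort on a second platform, and the 50-250 model-size grid.
#'
#' @param scale `"tiny"` or `"paper_shape"`.
#' @param seed base seed recorded in the config.
#' @return a named configuration list accepted by [runPipeline()].
#' @export
makeDemoConfig <- function(scale = c("tiny", "paper_shape"), seed = 1L) {
  scale <- match.arg(scale)
  base <- list(
    frac_annotated = 0.9, n_cases = 11L, n_controls = 6L,
    frac_paired_lobes = 6 / 11, frac_explant = 5 / 11,
    effect_size = 1.5, batch_effect = 1.0, within_patient_rho = 0.675,
    baseline_mean = 7, baseline_sd = 3.3, noise_sd = 1)
  train <- c(list(n_features = if (scale == "tiny") 2000L else 5000L,
                  n_diff = if (scale == "tiny") 100L else 150L,
                  n_batch = if (scale == "tiny") 50L else 100L), base)
  cfg <- list(
    seed = as.integer(seed),
    simulate = list(
      train = train,
      validation = list(n_cases = 31L, n_controls = 15L,
                        frac_paired_lobes = 0, frac_explant = 1),
      platform2 = list(frac_one_to_one = 0.80, frac_many_to_one = 0.09,
                       frac_one_to_many = 0.09, drop_frac = 0.02,
                       scale_sd = 0.15, shift_sd = 0.3, noise_sd = 0.1)),
    input = list(),
    preprocess = list(min_mean = 4, cov_fraction = 0.10,
                      prefer_lobe = "upper"),
    model = list(
      contrast = "all",
      grid = if (scale == "tiny") c(20L, 40L, 60L)
             else seq(50L, 250L, by = 10L),
      r = 2L, prior = c(100, 4),
      mcmc_loo = if (scale == "tiny")
        list(iterations = 400L, burn_in = 100L)
        else list(iterations = 2000L, burn_in = 500L),
      mcmc_final = if (scale == "tiny")
        list(iterations = 2000L, burn_in = 500L)
        else list(iterations = 10000L, burn_in = 2000L)),
    validate = list(cutoff = "youden"))
  validatePipelineConfig(cfg)
  cfg
}

#' Read / write a pipeline configuration (YAML or JSON)
#'
#' @param path config file; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return the validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  validatePipelineConfig(cfg)
  cfg
}

#' @rdname readPipelineConfig
#' @param config configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  } else yaml::write_yaml(config, path)
  invisible(path)
}

.stage <- function(name, log, expr) {
  log(paste0("stage ", name, " ..."))
  tryCatch(expr, error = function(e)
    stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the end-to-end signature workflow
#'
#' Executes simulate (or load) -> filter -> unsupervised exploration ->
#' differential expression -> lobe-pair collapse -> leave-one-out size
#' tuning -> final training -> second-platform validation-cohort simulation
#' -> cross-platform transfer -> diagnostic evaluation, writing every
#' artifact plus a manifest into `out_dir`. Rerunning with an identical
#' configuration reproduces all numeric outputs bit-for-bit (no timestamps
#' are recorded).
#'
#' @param config configuration list (see [makeDemoConfig()]).
#' @param out_dir output directory (created; existing files overwritten).
#' @return (invisibly) a list with the in-memory results: `model`,
#'   `selection`, `report`, `summary`.
#' @export
runPipeline <- function(config, out_dir) {
  validatePipelineConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  if (file.exists(log_path)) unlink(log_path)
  log <- function(...) cat(..., "\n", sep = "", file = log_path,
                           append = TRUE)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
    stop(e)
  }
  tryCatch({
    seed <- config$seed
    shapes <- list()
    note_shape <- function(stage, x) {
      shapes[[stage]] <<- c(features = nrow(x), samples = ncol(x))
      log(stage, ": ", nrow(x), " features x ", ncol(x), " samples")
    }

    # --- training data -------------------------------------------------
    if (length(config$input) && nzchar(config$input$expression_path %||% "")) {
      sim <- NULL
      se <- .stage("load", log, {
        x <- readExpressionMatrix(config$input$expression_path,
                                  config$input$annotation_path)
        attachPhenotype(x, readPhenotypeTable(config$input$phenotype_path))
      })
      truth <- NULL
    } else {
      sim <- .stage("simulate", log, {
        cc <- do.call(SimulationConfig,
                      c(config$simulate$train,
                        list(seed = substreamSeed(seed, "train"))))
        simulateCohort(cc)
      })
      se <- sim$se
      truth <- sim$truth
    }
    note_shape("input", se)

    # --- preprocessing -------------------------------------------------
    filt <- .stage("filter", log,
                   filterFeatures(se, config$preprocess$min_mean))
    se_f <- filt$se
    note_shape("filtered", se_f)

    # --- unsupervised exploration on the high-CoV subset ---------------
    explore <- .stage("explore", log, {
      se_cov <- selectTopCoV(se_f, config$preprocess$cov_fraction)
      pca <- expressionPCA(se_cov, n_components = 2L)
      hc <- averageLinkage(pearsonDistance(se_cov))
      exportNewick(hc, file.path(out_dir, "dendrogram.nwk"))
      pc <- pairedCorrelation(se_f)
      ph <- phenoFrame(se_f)
      paired_pid <- names(which(table(
        ph$patient_id[ph$phenotype == 1L]) == 2L))
      icc <- NULL
      if (length(paired_pid) >= 2L) {
        sel <- ph$patient_id %in% paired_pid & ph$phenotype == 1L
        pcs <- expressionPCA(se_f[, sel], n_components = 1L)
        icc <- iccOneWay(pcs$scores[, 1L], ph$patient_id[sel])
      }
      list(variance_explained_pc12 = sum(pca$variance_explained[1:2]),
           matched_r = pc$matched, unmatched_r = pc$unmatched, icc = icc)
    })

    # --- differential expression: biopsy vs explant --------------------
    de <- .stage("diffexpr", log, {
      ph <- phenoFrame(se_f)
      one_per_pat <- collapseLobePairs(se_f,
                                       config$preprocess$prefer_lobe)
      php <- phenoFrame(one_per_pat)
      sel <- php$sample_type %in% c("biopsy", "explant")
      out <- NULL
      if (sum(php$sample_type[sel] == "biopsy") >= 2L &&
          sum(php$sample_type[sel] == "explant") >= 2L) {
        mt <- moderatedT(one_per_pat[, sel],
                         as.integer(php$sample_type[sel] == "explant"))
        out <- list(n_significant_fdr10 = sum(mt$q <= 0.10),
                    excess_p05 = pvalueHistogram(mt$p)$excess)
      }
      out
    })

    # --- training set and model-size tuning -----------------------------
    train_se <- .stage("collapse", log, {
      x <- collapseLobePairs(se_f, config$preprocess$prefer_lobe)
      ph <- phenoFrame(x)
      keep <- switch(config$model$contrast %||% "all",
        all = rep(TRUE, ncol(x)),
        biopsy = ph$sample_type %in% c("biopsy", "control"),
        explant = ph$sample_type %in% c("explant", "control"))
      x[, keep]
    })
    note_shape("training", train_se)
    y <- phenoFrame(train_se)$phenotype

    selection <- .stage("tune", log, {
      mc <- config$model$mcmc_loo
      tuneModelSize(train_se, y, grid = config$model$grid,
                    r = config$model$r, prior = config$model$prior,
                    iterations = mc$iterations, burn_in = mc$burn_in,
                    seed = substreamSeed(seed, "tune"))
    })
    write.table(selectionTrace(selection),
                file.path(out_dir, "selection_trace.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

    model <- .stage("train", log, {
      mc <- config$model$mcmc_final
      trainSignature(train_se, y, k = chosenSize(selection),
                     r = config$model$r, prior = config$model$prior,
                     iterations = mc$iterations, burn_in = mc$burn_in,
                     seed = substreamSeed(seed, "train_final"))
    })
    writeSignatureModel(model, file.path(out_dir, "model"))

    # --- validation cohort on a second platform ------------------------
    report <- NULL
    val <- NULL
    if (!is.null(truth)) {
      val <- .stage("transfer", log, {
        vc <- do.call(SimulationConfig, c(
          config$simulate$train[c("n_features", "frac_annotated", "n_diff",
                                  "n_batch", "effect_size", "batch_effect",
                                  "within_patient_rho", "baseline_mean",
                                  "baseline_sd", "noise_sd")],
          config$simulate$validation,
          list(seed = substreamSeed(seed, "validation"))))
        vsim <- simulateCohort(vc, truth = truth)
        p2 <- do.call(simulateSecondPlatform, c(
          list(se = vsim$se, seed = substreamSeed(seed, "platform2")),
          config$simulate$platform2))
        mapping <- deriveMapping(annotation(se), annotation(p2$se))
        mp <- mapExpression(p2$se, mapping, signatureFeatures(model))
        xn <- scaleShiftNormalize(mp$exprs, model@center, model@scale)
        proj <- projectValidation(model, xn)
        same <- predictProbability(model, vsim$se)
        list(probabilities = proj$probabilities,
             same_platform = same,
             labels = phenoFrame(vsim$se)$phenotype,
             coverage = mp$report$coverage,
             transfer_mad = mean(abs(proj$probabilities - same)))
      })
      report <- .stage("validate", log,
                       validationReport(val$probabilities, val$labels,
                                        config$validate$cutoff))
      write.table(
        data.frame(sample_id = names(val$probabilities),
                   probability = sprintf("%.17g", val$probabilities),
                   phenotype = val$labels),
        file.path(out_dir, "validation_probabilities.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    }

    # --- manifest and summary -------------------------------------------
    summary <- list(
      filter_report = filt$report,
      explore = list(variance_explained_pc12 =
                       explore$variance_explained_pc12,
                     matched_r = explore$matched_r,
                     unmatched_r = explore$unmatched_r,
                     icc_pc1 = explore$icc$icc %||% NA,
                     icc_p = explore$icc$p_value %||% NA),
      diffexpr = de,
      chosen_k = chosenSize(selection),
      loo = selectionTrace(selection)[
        selectionTrace(selection)$k == chosenSize(selection), ],
      validation = if (!is.null(report)) list(
        auc = reportAUC(report),
        youden_cutoff = report@youden$cutoff,
        sensitivity = report@confusion$sensitivity,
        specificity = report@confusion$specificity,
        accuracy = report@confusion$accuracy,
        wilcoxon_p = report@wilcoxon$p_value,
        coverage = val$coverage,
        transfer_mad = val$transfer_mad) else NULL)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(package_version =
                       as.character(packageVersion("bprsig")),
                     config = config, shapes = shapes)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(model = model, selection = selection, report = report,
                   summary = summary))
  }, error = on_fail)
}
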