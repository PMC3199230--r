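#' @import methods
NULL

#' Configuration of the synthetic cohort generator
#'
#' Parameters of the seeded generator that emulates a two-group whole-lung
#' microarray cohort: paired upper/lower-lobe samples sharing a patient, a
#' biopsy-versus-explant batch split within cases, truly differential
#' features with a log2 mean shift, and within-patient residual correlation.
#'
#' @slot n_features number of array features.
#' @slot frac_annotated fraction of features carrying a gene identifier.
#' @slot n_cases,n_controls numbers of case and control patients.
#' @slot frac_paired_lobes fraction of case patients contributing an
#'   upper/lower lobe pair.
#' @slot frac_explant fraction of case patients sampled at explant
#'   (transplant) rather than at diagnostic biopsy.
#' @slot n_diff number of truly differential features.
#' @slot n_batch number of features shifted in explant samples.
#' @slot effect_size case-minus-control mean shift (log2 units) on
#'   differential features; each feature gets a random sign.
#' @slot batch_effect log2 shift added to batch features in explants.
#' @slot within_patient_rho residual correlation of lobe-pair samples,
#'   realized through a shared per-patient effect with variance
#'   `rho/(1-rho) * noise_sd^2`.
#' @slot baseline_mean,baseline_sd distribution of per-feature baseline
#'   log2 expression.
#' @slot noise_sd per-measurement Gaussian noise SD (log2 units).
#' @slot seed integer seed; the generator is deterministic given the seed.
#'
#' @seealso [simulateCohort()], [simulateSecondPlatform()]
#' @export
setClass("SimulationConfig",
  representation(
    n_features = "integer", frac_annotated = "numeric",
    n_cases = "integer", n_controls = "integer",
    frac_paired_lobes = "numeric", frac_explant = "numeric",
    n_diff = "integer", n_batch = "integer",
    effect_size = "numeric", batch_effect = "numeric",
    within_patient_rho = "numeric",
    baseline_mean = "numeric", baseline_sd = "numeric",
    noise_sd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  fr <- c(frac_annotated = object@frac_annotated,
          frac_paired_lobes = object@frac_paired_lobes,
          frac_explant = object@frac_explant)
  bad <- fr < 0 | fr > 1
  if (any(bad))
    msg <- c(msg, paste0(names(fr)[bad][1L], " must lie in [0, 1]"))
  if (object@n_diff + object@n_batch > object@n_features)
    msg <- c(msg, "n_diff + n_batch must not exceed n_features")
  if (object@noise_sd <= 0) msg <- c(msg, "noise_sd must be > 0")
  if (object@baseline_sd < 0) msg <- c(msg, "baseline_sd must be >= 0")
  if (object@within_patient_rho < 0 || object@within_patient_rho >= 1)
    msg <- c(msg, "within_patient_rho must lie in [0, 1)")
  if (object@n_cases < 1 || object@n_controls < 1)
    msg <- c(msg, "need at least one case and one control")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults are sized to the training study the generator emulates: 11 case
#' patients (6 biopsy, 5 explant; 6 contributing lobe pairs) and 6 normal
#' controls, with baseline spread and within-patient correlation chosen so
#' matched lobe pairs correlate at about 0.93 and unmatched case pairs at
#' about 0.78 across features.
#'
#' @param n_features,frac_annotated,n_cases,n_controls,frac_paired_lobes
#'   see class slots.
#' @param frac_explant,n_diff,n_batch,effect_size,batch_effect see slots.
#' @param within_patient_rho,baseline_mean,baseline_sd,noise_sd,seed see
#'   slots.
#' @return a validated [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(n_features = 500, seed = 7)
#' cfg
#' @export
SimulationConfig <- function(n_features = 5000L, frac_annotated = 0.9,
                             n_cases = 11L, n_controls = 6L,
                             frac_paired_lobes = 6 / 11,
                             frac_explant = 5 / 11,
                             n_diff = 150L, n_batch = 100L,
                             effect_size = 1.5, batch_effect = 1.0,
                             within_patient_rho = 0.675,
                             baseline_mean = 7, baseline_sd = 3.3,
                             noise_sd = 1, seed = 1L) {
  new("SimulationConfig",
      n_features = as.integer(n_features),
      frac_annotated = frac_annotated,
      n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
      frac_paired_lobes = frac_paired_lobes, frac_explant = frac_explant,
      n_diff = as.integer(n_diff), n_batch = as.integer(n_batch),
      effect_size = effect_size, batch_effect = batch_effect,
      within_patient_rho = within_patient_rho,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      noise_sd = noise_sd, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@n_features, "features,",
      object@n_cases, "cases /", object@n_controls, "controls\n")
  cat("  differential:", object@n_diff, "features at delta =",
      object@effect_size, "| batch:", object@n_batch, "features at gamma =",
      object@batch_effect, "\n")
  cat("  paired lobes:", round(object@frac_paired_lobes * object@n_cases),
      "patients | explants:", round(object@frac_explant * object@n_cases),
      "| rho =", object@within_patient_rho,
      "| sigma =", object@noise_sd, "| seed =", object@seed, "\n")
})

#' Ground truth of a simulated cohort
#'
#' Records the latent structure of a generated cohort so downstream checks
#' can compare estimates against it, and so a second cohort (e.g. an
#' independent validation set) can be drawn from the same population.
#'
#' @slot baseline named numeric, per-feature baseline log2 mean.
#' @slot diff_effects named numeric, signed log2 shift of each truly
#'   differential feature (case minus control).
#' @slot batch_features character, features shifted in explant samples.
#' @slot annotation named list of character vectors, gene identifiers per
#'   feature (empty for unannotated features).
#' @export
setClass("SimulationTruth",
  representation(baseline = "numeric", diff_effects = "numeric",
                 batch_features = "character", annotation = "list"))

setValidity("SimulationTruth", function(object) {
  feat <- names(object@baseline)
  if (!all(names(object@diff_effects) %in% feat))
    return("differential feature IDs must be generated feature IDs")
  if (!all(object@batch_features %in% feat))
    return("batch feature IDs must be generated feature IDs")
  TRUE
})

setMethod("show", "SimulationTruth", function(object) {
  cat("SimulationTruth:", length(object@baseline), "features,",
      length(object@diff_effects), "differential,",
      length(object@batch_features), "batch-affected\n")
})

#' Trained gene-expression signature
#'
#' The frozen artifact of supervised training: the selected feature panel,
#' its training centering/scaling, the training-only SVD loadings and
#' singular values defining the metagene factors, and the retained posterior
#' coefficient draws of the Bayesian probit regression.
#'
#' @slot features character, selected feature IDs (size k panel).
#' @slot center,scale named numeric, per-feature training mean and SD used
#'   to standardize expression before projection.
#' @slot loadings k x r matrix of left singular vectors (orthonormal
#'   columns).
#' @slot singular_values length-r positive, nonincreasing singular values.
#' @slot draws retained MCMC draws of (intercept, factor coefficients),
#'   one row per draw.
#' @slot k,r panel size and number of factors.
#' @slot prior prior variances of (intercept, coefficients).
#' @slot mcmc list: iterations, burn_in, seed.
#' @slot labels list describing the phenotype coding (case = 1).
#' @seealso [trainSignature()], [predictProbability()]
#' @export
setClass("SignatureModel",
  representation(features = "character", center = "numeric",
                 scale = "numeric", loadings = "matrix",
                 singular_values = "numeric", draws = "matrix",
                 k = "integer", r = "integer", prior = "numeric",
                 mcmc = "list", labels = "list"))

setValidity("SignatureModel", function(object) {
  msg <- character(0)
  k <- length(object@features)
  r <- object@r
  if (object@k != k) msg <- c(msg, "k must equal length(features)")
  if (k < r) msg <- c(msg, "need at least as many features as factors")
  if (!identical(dim(object@loadings), c(k, as.integer(r))))
    msg <- c(msg, "loadings must be k x r")
  if (length(object@singular_values) != r ||
      any(object@singular_values <= 0) ||
      is.unsorted(rev(object@singular_values)))
    msg <- c(msg, "singular values must be positive and nonincreasing")
  ortho <- crossprod(object@loadings) - diag(r)
  if (max(abs(ortho)) > 1e-6)
    msg <- c(msg, "loading columns must be orthonormal")
  if (ncol(object@draws) != r + 1L)
    msg <- c(msg, "draws must have intercept + r coefficient columns")
  if (!all(is.finite(object@draws))) msg <- c(msg, "non-finite draws")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel:", object@k, "features,", object@r,
      "SVD factors,", nrow(object@draws), "posterior draws\n")
  cat("  MCMC:", object@mcmc$iterations, "iterations,",
      object@mcmc$burn_in, "burn-in, seed", object@mcmc$seed, "\n")
  cat("  posterior mean coefficients:",
      paste(sprintf("%.3f", colMeans(object@draws)), collapse = ", "), "\n")
})

#' @describeIn SignatureModel-class selected feature IDs.
#' @param object,x a `SignatureModel`.
#' @export
setGeneric("signatureFeatures", function(object)
  standardGeneric("signatureFeatures"))

#' @rdname SignatureModel-class
#' @export
setMethod("signatureFeatures", "SignatureModel",
          function(object) object@features)

#' @describeIn SignatureModel-class k x r training SVD loadings.
#' @export
setGeneric("factorLoadings", function(object)
  standardGeneric("factorLoadings"))

#' @rdname SignatureModel-class
#' @export
setMethod("factorLoadings", "SignatureModel", function(object)
  object@loadings)

#' @describeIn SignatureModel-class retained posterior coefficient draws.
#' @export
setGeneric("posteriorDraws", function(object)
  standardGeneric("posteriorDraws"))

#' @rdname SignatureModel-class
#' @export
setMethod("posteriorDraws", "SignatureModel", function(object) object@draws)

#' Leave-one-out model-size selection trace
#'
#' Per candidate panel size: the leave-one-out sum of deviances and
#' misclassification rate, plus the chosen size (smallest size attaining
#' the minimum sum of deviances).
#'
#' @slot trace data.frame with columns `k`, `sum_deviance`,
#'   `misclassification`.
#' @slot chosen_k the selected panel size.
#' @seealso [tuneModelSize()]
#' @export
setClass("ModelSelectionTrace",
  representation(trace = "data.frame", chosen_k = "integer"))

setValidity("ModelSelectionTrace", function(object) {
  tr <- object@trace
  need <- c("k", "sum_deviance", "misclassification")
  if (!all(need %in% names(tr))) return("trace lacks required columns")
  if (any(tr$sum_deviance < 0)) return("sum_deviance must be >= 0")
  if (any(tr$misclassification < 0 | tr$misclassification > 1))
    return("misclassification must lie in [0, 1]")
  if (!(object@chosen_k %in% tr$k)) return("chosen_k must be on the grid")
  TRUE
})

setMethod("show", "ModelSelectionTrace", function(object) {
  cat("ModelSelectionTrace over", nrow(object@trace), "candidate sizes;",
      "chosen k =", object@chosen_k, "\n")
  print(object@trace, row.names = FALSE)
})

#' @describeIn ModelSelectionTrace-class the chosen panel size.
#' @param object a `ModelSelectionTrace`.
#' @export
setGeneric("chosenSize", function(object) standardGeneric("chosenSize"))

#' @rdname ModelSelectionTrace-class
#' @export
setMethod("chosenSize", "ModelSelectionTrace", function(object)
  object@chosen_k)

#' @describeIn ModelSelectionTrace-class the per-size metric table.
#' @export
setGeneric("selectionTrace", function(object)
  standardGeneric("selectionTrace"))

#' @rdname ModelSelectionTrace-class
#' @export
setMethod("selectionTrace", "ModelSelectionTrace", function(object)
  object@trace)

#' Diagnostic evaluation of predicted probabilities
#'
#' Per-sample predicted probabilities with their ROC curve, AUC, the Youden
#' operating point, the confusion metrics at that point, and the Wilcoxon
#' rank-sum association test.
#'
#' @slot probabilities named numeric in (0,1).
#' @slot labels named integer 0/1 truth.
#' @slot roc data.frame of (cutoff, sensitivity, specificity).
#' @slot auc area under the ROC curve (Mann-Whitney concordance).
#' @slot youden list: cutoff, J.
#' @slot confusion list of counts and rate metrics at the cutoff.
#' @slot wilcoxon list: U statistic, p_value.
#' @seealso [validationReport()]
#' @export
setClass("ValidationReport",
  representation(probabilities = "numeric", labels = "integer",
                 roc = "data.frame", auc = "numeric", youden = "list",
                 confusion = "list", wilcoxon = "list"))

setValidity("ValidationReport", function(object) {
  if (length(object@probabilities) != length(object@labels))
    return("probabilities and labels differ in length")
  if (object@auc < 0 || object@auc > 1) return("AUC must lie in [0, 1]")
  TRUE
})

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport:", sum(object@labels == 1L), "cases /",
      sum(object@labels == 0L), "controls\n")
  cat(sprintf("  AUC %.3f | Youden cutoff %.3f (J = %.3f)\n",
              object@auc, object@youden$cutoff, object@youden$J))
  cm <- object@confusion
  cat(sprintf(
    "  sens %d%% spec %d%% PPV %s NPV %s accuracy %d%% | Wilcoxon p = %.3g\n",
    round(cm$sensitivity * 100), round(cm$specificity * 100),
    if (is.na(cm$ppv)) "NA" else paste0(round(cm$ppv * 100), "%"),
    if (is.na(cm$npv)) "NA" else paste0(round(cm$npv * 100), "%"),
    round(cm$accuracy * 100), object@wilcoxon$p_value))
})

#' @describeIn ValidationReport-class the AUC.
#' @param object a `ValidationReport`.
#' @export
setGeneric("reportAUC", function(object) standardGeneric("reportAUC"))

#' @rdname ValidationReport-class
#' @export
setMethod("reportAUC", "ValidationReport", function(object) object@auc)
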