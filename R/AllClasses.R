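#' @include AllGenerics.R
NULL

## Core S4 classes: acquisition scheme, model parameter sets, fit results,
## and the lesion-level cohort container.

#' The 18 quantitative diffusion metrics
#'
#' Metric naming follows the `ModelName_ParameterName` convention. D-type
#' metrics (MEM_ADC, SEM_DDC, IVIM_D, IVIM_Dstar, DKI_D, IVIM-DKI_D,
#' IVIM-DKI_Dp, CTRW_D, FROC_D) are expressed in 1e-3 mm^2/s; FROC_mu is
#' reported on the scale of the literature (values around 7, conventionally
#' quoted in micrometres); the remaining shape metrics are dimensionless.
#'
#' @return Character vector of the 18 metric names.
#' @export
#' @examples
#' dwiMetricNames()
dwiMetricNames <- function() {
  c("MEM_ADC",
    "SEM_DDC", "SEM_alpha",
    "IVIM_D", "IVIM_Dstar", "IVIM_f",
    "DKI_D", "DKI_K",
    "IVIM-DKI_D", "IVIM-DKI_Dp", "IVIM-DKI_f", "IVIM-DKI_K",
    "CTRW_D", "CTRW_alpha", "CTRW_beta",
    "FROC_D", "FROC_beta", "FROC_mu")
}

#' Supported signal-model families
#'
#' @return Character vector of the seven family identifiers.
#' @export
dwiModelFamilies <- function() {
  c("MEM", "SEM", "IVIM", "DKI", "IVIM_DKI", "CTRW", "FROC")
}

## family -> ordered parameter slots (excluding s0)
.familyParams <- list(
  MEM      = c("adc"),
  SEM      = c("ddc", "alpha"),
  IVIM     = c("d", "dstar", "f"),
  DKI      = c("d", "k"),
  IVIM_DKI = c("d", "dp", "f", "k"),
  CTRW     = c("d", "alpha", "beta"),
  FROC     = c("d", "beta", "mu"))

## family/parameter -> metric name
.familyMetricMap <- list(
  MEM      = c(adc = "MEM_ADC"),
  SEM      = c(ddc = "SEM_DDC", alpha = "SEM_alpha"),
  IVIM     = c(d = "IVIM_D", dstar = "IVIM_Dstar", f = "IVIM_f"),
  DKI      = c(d = "DKI_D", k = "DKI_K"),
  IVIM_DKI = c(d = "IVIM-DKI_D", dp = "IVIM-DKI_Dp", f = "IVIM-DKI_f",
               k = "IVIM-DKI_K"),
  CTRW     = c(d = "CTRW_D", alpha = "CTRW_alpha", beta = "CTRW_beta"),
  FROC     = c(d = "FROC_D", beta = "FROC_beta", mu = "FROC_mu"))

## ------------------------------------------------------------------ scheme

#' Acquisition b-value scheme
#'
#' An ordered set of diffusion weightings defining a multi-b-value DWI
#' acquisition. Values are in s/mm^2, non-negative and strictly increasing.
#'
#' @slot bvalues numeric vector of b-values (s/mm^2).
#' @aliases BValueScheme-class
#' @export
setClass("BValueScheme", slots = c(bvalues = "numeric"))

setValidity("BValueScheme", function(object) {
  b <- object@bvalues
  if (length(b) < 1L) return("scheme must contain at least one b-value")
  if (anyNA(b) || any(!is.finite(b))) return("b-values must be finite")
  if (any(b < 0)) return("b-values must be non-negative")
  if (any(diff(b) <= 0)) return("b-values must be strictly increasing")
  TRUE
})

#' Construct a b-value scheme
#'
#' @param bvalues numeric vector of b-values (s/mm^2); will be validated as
#'   non-negative and strictly increasing.
#' @return A [BValueScheme-class] object.
#' @export
#' @examples
#' bValueScheme(c(0, 500, 1000, 2000, 3000))
bValueScheme <- function(bvalues) {
  new("BValueScheme", bvalues = as.numeric(bvalues))
}

#' Default 12-point b-value scheme
#'
#' A 12-point scheme spanning 0-3000 s/mm^2 with dense low-b sampling for
#' perfusion sensitivity and high b-values for the non-Gaussian models.
#'
#' @return A [BValueScheme-class] with b =
#'   0, 50, 100, 150, 200, 500, 800, 1000, 1500, 2000, 2500, 3000 s/mm^2.
#' @export
defaultBScheme <- function() {
  bValueScheme(c(0, 50, 100, 150, 200, 500, 800, 1000, 1500, 2000, 2500, 3000))
}

#' @rdname bValues
#' @export
setMethod("bValues", "BValueScheme", function(x) x@bvalues)

setMethod("show", "BValueScheme", function(object) {
  cat("BValueScheme with", length(object@bvalues), "b-values (s/mm^2):\n")
  cat(" ", paste(object@bvalues, collapse = ", "), "\n")
})

## --------------------------------------------------------------- paramset

#' Parameter set of one diffusion signal model
#'
#' Tagged parameter vector for one of the seven signal-model families.
#' Diffusivity-type parameters (`adc`, `ddc`, `d`, `dstar`, `dp`) are
#' stored in the reporting unit of 1e-3 mm^2/s; `mu` on the literature
#' scale (around 7); `f`, `alpha`, `beta`, `k` are dimensionless. The
#' signal equations convert to SI internally so that b * D is
#' dimensionless.
#'
#' @slot family character, one of [dwiModelFamilies()].
#' @slot s0 baseline (b = 0) signal, arbitrary units, > 0.
#' @slot params named numeric vector of family parameters.
#' @aliases ModelParamSet-class
#' @export
setClass("ModelParamSet",
         slots = c(family = "character", s0 = "numeric", params = "numeric"))

setValidity("ModelParamSet", function(object) {
  fam <- object@family
  if (length(fam) != 1L || !fam %in% dwiModelFamilies())
    return(sprintf("unknown model family '%s'", paste(fam, collapse = ",")))
  if (length(object@s0) != 1L || !is.finite(object@s0) || object@s0 <= 0)
    return("s0 must be a positive finite scalar")
  p <- object@params
  want <- .familyParams[[fam]]
  if (!identical(sort(names(p)), sort(want)))
    return(sprintf("%s parameters must be exactly {%s}", fam,
                   paste(want, collapse = ", ")))
  if (anyNA(p) || any(!is.finite(p))) return("parameters must be finite")
  ## fits may clip a diffusivity to the zero boundary, so the container
  ## admits 0; the signal equations themselves require > 0
  diffs <- intersect(names(p), c("adc", "ddc", "d"))
  if (any(p[diffs] < 0)) return("diffusivities must be non-negative")
  if ("f" %in% names(p) && (p[["f"]] < 0 || p[["f"]] >= 1))
    return("perfusion fraction f must lie in [0, 1)")
  for (nm in intersect(names(p), c("alpha", "beta")))
    if (p[[nm]] <= 0 || p[[nm]] > 1)
      return(sprintf("%s must lie in (0, 1]", nm))
  if ("k" %in% names(p) && p[["k"]] < 0) return("kurtosis K must be >= 0")
  if ("mu" %in% names(p) && p[["mu"]] <= 0) return("mu must be positive")
  if ("dstar" %in% names(p) && p[["dstar"]] <= p[["d"]])
    return("pseudo-diffusion D* must exceed tissue diffusion D")
  if ("dp" %in% names(p) && p[["dp"]] <= p[["d"]])
    return("pseudo-diffusion Dp must exceed tissue diffusion D")
  TRUE
})

#' Construct a model parameter set
#'
#' @param model model family, one of [dwiModelFamilies()]. (The formal is
#'   named `model` rather than `family` so that the `f =` perfusion
#'   fraction argument cannot partially match it.)
#' @param ... named family parameters (see [ModelParamSet-class]), e.g.
#'   `adc =` for MEM, `d =, dstar =, f =` for IVIM. Diffusivities in
#'   1e-3 mm^2/s.
#' @param s0 baseline signal (default 1).
#' @return A validated [ModelParamSet-class].
#' @export
#' @examples
#' modelParamSet("MEM", adc = 0.87)
#' modelParamSet("CTRW", d = 1.01, alpha = 0.83, beta = 0.76)
modelParamSet <- function(model, ..., s0 = 1) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.numeric(dots[[1]]) &&
      !is.null(names(dots[[1]])))
    dots <- as.list(dots[[1]])
  p <- unlist(dots)
  want <- .familyParams[[match.arg(model, dwiModelFamilies())]]
  new("ModelParamSet", family = model, s0 = as.numeric(s0),
      params = p[want])
}

#' @rdname modelFamily
#' @export
setMethod("modelFamily", "ModelParamSet", function(x) x@family)

#' Extract parameters as named metric values
#'
#' Converts a parameter set into its `ModelName_ParameterName` metric
#' representation (e.g. the CTRW set maps to `CTRW_D`, `CTRW_alpha`,
#' `CTRW_beta`).
#'
#' @param params a [ModelParamSet-class].
#' @return Named numeric vector of metric values.
#' @export
paramMetrics <- function(params) {
  stopifnot(is(params, "ModelParamSet"))
  map <- .familyMetricMap[[params@family]]
  setNames(params@params[names(map)], unname(map))
}

#' Build a parameter set from metric values
#'
#' Inverse of [paramMetrics()]: picks the metrics belonging to `family`
#' out of a named 18-metric vector.
#'
#' @param family model family.
#' @param metrics named numeric vector containing at least the metrics of
#'   `family`.
#' @param s0 baseline signal.
#' @return A [ModelParamSet-class].
#' @export
paramSetFromMetrics <- function(family, metrics, s0 = 1) {
  map <- .familyMetricMap[[match.arg(family, dwiModelFamilies())]]
  vals <- metrics[unname(map)]
  if (anyNA(vals))
    stop("metrics missing for family ", family, ": ",
         paste(setdiff(unname(map), names(metrics)), collapse = ", "))
  modelParamSet(family, setNames(as.numeric(vals), names(map)), s0 = s0)
}

setMethod("show", "ModelParamSet", function(object) {
  cat("ModelParamSet [", object@family, "], s0 = ",
      format(object@s0, digits = 4), "\n", sep = "")
  print(round(object@params, 5))
})

## --------------------------------------------------------------- fit result

#' Result of one model fit
#'
#' @slot params fitted [ModelParamSet-class].
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot nIter number of optimizer iterations (best start).
#' @slot atBound named logical; `TRUE` where a parameter sits at a box
#'   constraint (within tolerance).
#' @slot message diagnostic message from the optimizer.
#' @aliases FitResult-class
#' @export
setClass("FitResult",
         slots = c(params = "ModelParamSet", rss = "numeric",
                   converged = "logical", nIter = "integer",
                   atBound = "logical", message = "character"))

setValidity("FitResult", function(object) {
  if (object@converged && !is.finite(object@rss))
    return("a converged fit must have finite rss")
  TRUE
})

#' @rdname modelFamily
#' @export
setMethod("modelFamily", "FitResult", function(x) x@params@family)

#' Fitted parameters of a FitResult
#'
#' @param fit a [FitResult-class].
#' @return The fitted [ModelParamSet-class].
#' @export
fitParams <- function(fit) fit@params

setMethod("show", "FitResult", function(object) {
  cat("FitResult [", object@params@family, "] ",
      if (object@converged) "converged" else "NOT converged",
      ", rss = ", format(object@rss, digits = 6),
      ", iterations = ", object@nIter, "\n", sep = "")
  v <- c(s0 = object@params@s0, object@params@params)
  print(round(v, 5))
  if (any(object@atBound))
    cat("at bound:", paste(names(object@atBound)[object@atBound],
                           collapse = ", "), "\n")
})

## ------------------------------------------------------------------ cohort

#' Lesion-level diffusion cohort
#'
#' A `SummarizedExperiment` whose rows are the 18 diffusion metrics and
#' whose columns are lesions. Assays hold metric matrices (`"truth"` for
#' generator ground truth, `"reader1"`/`"reader2"` for the two reader
#' replicates, `"measured"` for the reader-averaged working values);
#' `colData` carries the clustered clinical annotation (patient id, age,
#' PSA, PSAD, DRE, zone, PI-RADS, Gleason grade group, csPCa label,
#' lesion size, vendor and train/test/external split).
#'
#' @aliases DiffusionCohort-class
#' @export
setClass("DiffusionCohort",
         contains = "SummarizedExperiment")

setValidity("DiffusionCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("lesion_id", "patient_id", "zone", "gg", "cspca")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData lacks columns:", paste(miss, collapse = ", ")))
  if (!all(rownames(object) == dwiMetricNames()))
    return("rows must be the 18 diffusion metrics, in canonical order")
  if (!all(cd$zone %in% c("PZ", "TZ"))) return("zone must be PZ or TZ")
  if (!all(cd$gg %in% 0:5)) return("gg must be an integer grade group 0-5")
  if (!identical(as.integer(cd$cspca), as.integer(cd$gg >= 2L)))
    return("label inconsistency: cspca must equal (gg >= 2)")
  if ("split" %in% colnames(cd)) {
    bad <- vapply(split(as.character(cd$split), as.character(cd$patient_id)),
                  function(s) length(unique(s)) > 1L, logical(1))
    if (any(bad))
      return("split must be assigned at patient level (no patient straddles splits)")
  }
  TRUE
})

#' Construct a DiffusionCohort
#'
#' @param lesionData data.frame with one row per lesion; must contain
#'   `lesion_id`, `patient_id`, `zone`, `gg`, `cspca`.
#' @param ... named metric matrices (metrics x lesions), e.g.
#'   `truth =`, `measured =`; rows must be [dwiMetricNames()].
#' @param metadata list of run metadata (config, seed).
#' @return A [DiffusionCohort-class].
#' @export
DiffusionCohort <- function(lesionData, ..., metadata = list()) {
  assays <- list(...)
  stopifnot(length(assays) >= 1L, !is.null(names(assays)))
  assays <- lapply(assays, function(m) {
    m <- as.matrix(m)
    stopifnot(identical(rownames(m), dwiMetricNames()))
    colnames(m) <- as.character(lesionData$lesion_id)
    m
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(lesionData, check.names = FALSE),
    metadata = metadata)
  rownames(se) <- dwiMetricNames()
  colnames(se) <- as.character(lesionData$lesion_id)
  new("DiffusionCohort", se)
}

#' @rdname lesionData
#' @export
setMethod("lesionData", "DiffusionCohort",
          function(x) SummarizedExperiment::colData(x))

#' @rdname cohortTable
#' @export
setMethod("cohortTable", "DiffusionCohort", function(x, assay = "measured") {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  m <- t(SummarizedExperiment::assay(x, assay))
  out <- cbind(cd, as.data.frame(m, check.names = FALSE))
  rownames(out) <- NULL
  out
})

setMethod("show", "DiffusionCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("DiffusionCohort:", ncol(object), "lesions from",
      length(unique(cd$patient_id)), "patients\n")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object),
                         collapse = ", "), "\n")
  cat("  zones: PZ", sum(cd$zone == "PZ"), "/ TZ", sum(cd$zone == "TZ"),
      "; csPCa:", sum(cd$cspca == 1), "\n")
  if ("split" %in% colnames(cd)) {
    tab <- table(cd$split)
    cat("  split:", paste(names(tab), as.integer(tab), sep = "=",
                          collapse = ", "), "\n")
  }
})

## ------------------------------------------------------- analysis results

#' Bootstrap stability-selection result
#'
#' @slot frequencies named numeric; per-metric selection frequency over
#'   bootstrap resamples, in `[0, 1]`.
#' @slot stableSet character; metrics selected in more than `threshold`
#'   of the resamples.
#' @slot threshold stability frequency threshold (default 0.5).
#' @slot nBoot number of bootstrap resamples.
#' @slot lambdas numeric; cross-validated lambda chosen in each resample.
#' @slot nRedrawn number of degenerate (single-class) resamples redrawn.
#' @aliases StabilityResult-class
#' @export
setClass("StabilityResult",
         slots = c(frequencies = "numeric", stableSet = "character",
                   threshold = "numeric", nBoot = "integer",
                   lambdas = "numeric", nRedrawn = "integer"))

setMethod("show", "StabilityResult", function(object) {
  cat("StabilityResult over", object@nBoot, "bootstrap resamples\n")
  f <- sort(object@frequencies, decreasing = TRUE)
  print(round(head(f, 8), 3))
  cat("stable set (freq >", object@threshold, "):",
      if (length(object@stableSet)) paste(object@stableSet, collapse = ", ")
      else "(empty)", "\n")
})

#' GEE fit result
#'
#' @slot coefTable data.frame with columns `coefficient`, `or`,
#'   `robust_se`, `z`, `p` per covariate.
#' @slot corstr working correlation structure.
#' @slot alpha estimated exchangeable working correlation.
#' @slot nIter iterations used.
#' @slot converged logical.
#' @slot nClusters number of clusters (patients).
#' @aliases GEEResult-class
#' @export
setClass("GEEResult",
         slots = c(coefTable = "data.frame", corstr = "character",
                   alpha = "numeric", nIter = "integer",
                   converged = "logical", nClusters = "integer"))

setMethod("show", "GEEResult", function(object) {
  cat("GEEResult (binomial logit,", object@corstr,
      "working correlation, alpha =", round(object@alpha, 3), ")\n")
  cat(" ", object@nClusters, "clusters;",
      if (object@converged) "converged" else "NOT converged", "\n")
  print(round(object@coefTable, 4))
})

#' ROC-based model evaluation
#'
#' @slot auc area under the ROC curve.
#' @slot aucCI length-2 numeric confidence interval for the AUC.
#' @slot accuracy,sensitivity,specificity,ppv,npv confusion-matrix rates
#'   at the operating threshold.
#' @slot threshold operating threshold on the score scale.
#' @slot n number of evaluated lesions.
#' @slot prevalence outcome prevalence among evaluated lesions.
#' @aliases ModelEval-class
#' @export
setClass("ModelEval",
         slots = c(auc = "numeric", aucCI = "numeric", accuracy = "numeric",
                   sensitivity = "numeric", specificity = "numeric",
                   ppv = "numeric", npv = "numeric", threshold = "numeric",
                   n = "integer", prevalence = "numeric"))

setMethod("show", "ModelEval", function(object) {
  cat(sprintf("ModelEval: AUC %.3f (%.3f-%.3f), n = %d\n",
              object@auc, object@aucCI[1], object@aucCI[2], object@n))
  cat(sprintf("  acc %.2f sens %.2f spec %.2f ppv %.2f npv %.2f @ thr %.3f\n",
              object@accuracy, object@sensitivity, object@specificity,
              object@ppv, object@npv, object@threshold))
})

#' Decision curve
#'
#' @slot curve data.frame with columns `threshold`, `model`,
#'   `net_benefit`; includes the `treat_all` and `treat_none` references.
#' @slot prevalence outcome prevalence in the evaluated table.
#' @aliases DecisionCurve-class
#' @export
setClass("DecisionCurve",
         slots = c(curve = "data.frame", prevalence = "numeric"))

setMethod("show", "DecisionCurve", function(object) {
  cat("DecisionCurve over", length(unique(object@curve$threshold)),
      "thresholds;", "models:",
      paste(setdiff(unique(object@curve$model),
                    c("treat_all", "treat_none")), collapse = ", "), "\n")
  cat("  prevalence:", round(object@prevalence, 3), "\n")
})
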