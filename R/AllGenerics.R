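#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames colData colData<-
#' @importFrom S4Vectors DataFrame
#' @importFrom stats coef cor.test chisq.test glm.fit binomial
#'   integrate lm median p.adjust pnorm predict qlogis
#'   plogis qnorm quantile rbinom rlnorm rnorm runif sd setNames var
#'   wilcox.test model.matrix
#' @importFrom utils head modifyList read.csv write.csv
NULL

#' b-values of an acquisition scheme
#'
#' @param x a [BValueScheme-class] object.
#' @return Numeric vector of diffusion weightings in s/mm^2.
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' Lesion-level clinical annotation of a cohort
#'
#' @param x a [DiffusionCohort-class] object.
#' @return A `DataFrame` with one row per lesion.
#' @export
setGeneric("lesionData", function(x) standardGeneric("lesionData"))

#' Flat lesion-by-variable table of a cohort
#'
#' @param x a [DiffusionCohort-class] object.
#' @param assay name of the metric assay to flatten (e.g. `"measured"`).
#' @return A `data.frame` with one row per lesion: clinical covariates
#'   followed by the 18 diffusion metrics of the requested assay.
#' @export
setGeneric("cohortTable", function(x, assay = "measured") standardGeneric("cohortTable"))

#' Model family of a parameter set
#'
#' @param x a [ModelParamSet-class] or [FitResult-class] object.
#' @return Character scalar, one of `"MEM"`, `"SEM"`, `"IVIM"`, `"DKI"`,
#'   `"IVIM_DKI"`, `"CTRW"`, `"FROC"`.
#' @export
setGeneric("modelFamily", function(x) standardGeneric("modelFamily"))

#' Evaluate a forward diffusion signal model
#'
#' Dispatches on the family of `params` to the corresponding signal
#' equation ([memSignal()], [semSignal()], ...).
#'
#' @param params a [ModelParamSet-class].
#' @param b numeric vector of b-values (s/mm^2).
#' @return Numeric vector of modelled signal intensities (a.u.).
#' @export
setGeneric("dwiSignal", function(params, b) standardGeneric("dwiSignal"))
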