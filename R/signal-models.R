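#' @include AllGenerics.R AllClasses.R mittag-leffler.R
NULL

## Forward signal equations of the seven diffusion models.
##
## All diffusivity parameters are supplied in the reporting unit of
## 1e-3 mm^2/s (the convention of quantitative prostate DWI tables); the
## factor 1e-3 below converts to mm^2/s so that b * D is dimensionless
## for b in s/mm^2. FROC_mu is quoted on the literature scale (values
## around 7, conventionally micrometres) and enters the exponent as a
## length in mm (mu * 1e-3); see the methods vignette for the unit
## discussion.

.D_SCALE <- 1e-3
.MU_SCALE <- 1e-3

.checkB <- function(b) {
  if (any(!is.finite(b)) || any(b < 0)) stop("b-values must be finite and >= 0")
  b
}

.sigParams <- function(params, family) {
  stopifnot(is(params, "ModelParamSet"))
  if (params@family != family)
    stop("expected a ", family, " parameter set, got ", params@family)
  diffs <- intersect(names(params@params), c("adc", "ddc", "d"))
  if (any(params@params[diffs] <= 0))
    stop("signal evaluation requires a positive diffusivity")
  params
}

#' Mono-exponential (ADC) signal model
#'
#' `S(b) = S0 * exp(-b * ADC)`, the conventional Gaussian-diffusion model.
#'
#' @param params a `ModelParamSet("MEM", adc = ...)`; ADC in 1e-3 mm^2/s.
#' @param b numeric vector of b-values (s/mm^2).
#' @return Modelled signal, in `(0, S0]`.
#' @export
#' @examples
#' memSignal(modelParamSet("MEM", adc = 1), 1000)  # exp(-1)
memSignal <- function(params, b) {
  p <- .sigParams(params, "MEM")
  p@s0 * exp(-.checkB(b) * p@params[["adc"]] * .D_SCALE)
}

#' Stretched-exponential signal model
#'
#' `S(b) = S0 * exp(-(b * DDC)^alpha)`; `alpha` indexes intravoxel
#' heterogeneity and `alpha = 1` recovers the mono-exponential model.
#'
#' @param params a `ModelParamSet("SEM", ddc = , alpha = )`.
#' @inheritParams memSignal
#' @return Modelled signal.
#' @export
semSignal <- function(params, b) {
  p <- .sigParams(params, "SEM")
  p@s0 * exp(-(.checkB(b) * p@params[["ddc"]] * .D_SCALE)^p@params[["alpha"]])
}

#' Intravoxel incoherent motion (bi-exponential) signal model
#'
#' `S(b) = S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))`,
#' separating perfusion-driven pseudo-diffusion (`dstar`, fraction `f`)
#' from tissue diffusion (`d`).
#'
#' @param params a `ModelParamSet("IVIM", d = , dstar = , f = )`.
#' @inheritParams memSignal
#' @return Modelled signal.
#' @export
ivimSignal <- function(params, b) {
  p <- .sigParams(params, "IVIM")
  b <- .checkB(b)
  f <- p@params[["f"]]
  p@s0 * (f * exp(-b * p@params[["dstar"]] * .D_SCALE) +
            (1 - f) * exp(-b * p@params[["d"]] * .D_SCALE))
}

#' Diffusion kurtosis signal model
#'
#' `S(b) = S0 * exp(-b * D + b^2 * D^2 * K / 6)`. The quadratic kurtosis
#' expansion is only valid up to moderate b; beyond `bMaxDki` the value is
#' still returned but the range is flagged with a warning attribute
#' (`attr(., "b_beyond_validity")`).
#'
#' @param params a `ModelParamSet("DKI", d = , k = )`.
#' @inheritParams memSignal
#' @param bMaxDki validity guard for the kurtosis expansion
#'   (default 2000 s/mm^2).
#' @return Modelled signal; attribute `b_beyond_validity` marks b-values
#'   above `bMaxDki`.
#' @export
dkiSignal <- function(params, b, bMaxDki = 2000) {
  p <- .sigParams(params, "DKI")
  b <- .checkB(b)
  d <- p@params[["d"]] * .D_SCALE
  s <- p@s0 * exp(-b * d + b^2 * d^2 * p@params[["k"]] / 6)
  if (any(b > bMaxDki)) attr(s, "b_beyond_validity") <- b[b > bMaxDki]
  s
}

#' Hybrid IVIM-DKI signal model
#'
#' `S(b) = S0 * (f * exp(-b * Dp) + (1 - f) * exp(-b * D + b^2 D^2 K / 6))`,
#' combining a perfusion compartment with a kurtosis tissue compartment.
#'
#' @param params a `ModelParamSet("IVIM_DKI", d = , dp = , f = , k = )`.
#' @inheritParams dkiSignal
#' @return Modelled signal; attribute `b_beyond_validity` as for
#'   [dkiSignal()].
#' @export
ivimDkiSignal <- function(params, b, bMaxDki = 2000) {
  p <- .sigParams(params, "IVIM_DKI")
  b <- .checkB(b)
  d <- p@params[["d"]] * .D_SCALE
  f <- p@params[["f"]]
  s <- p@s0 * (f * exp(-b * p@params[["dp"]] * .D_SCALE) +
                 (1 - f) * exp(-b * d + b^2 * d^2 * p@params[["k"]] / 6))
  if (any(b > bMaxDki)) attr(s, "b_beyond_validity") <- b[b > bMaxDki]
  s
}

#' Fractional order calculus signal model (simplified b-value form)
#'
#' `S(b) = S0 * exp(-D * mu^(2 (beta - 1)) * b^beta)` with the spatial
#' constant `mu` entering as a length in mm (`mu` is supplied on the
#' conventional reporting scale, around 7, and rescaled by 1e-3).
#' `beta = 1` removes the `mu` dependence and recovers the
#' mono-exponential model.
#'
#' @param params a `ModelParamSet("FROC", d = , beta = , mu = )`.
#' @inheritParams memSignal
#' @return Modelled signal.
#' @export
frocSignal <- function(params, b) {
  p <- .sigParams(params, "FROC")
  b <- .checkB(b)
  beta <- p@params[["beta"]]
  mu <- p@params[["mu"]] * .MU_SCALE
  p@s0 * exp(-p@params[["d"]] * .D_SCALE * mu^(2 * (beta - 1)) * b^beta)
}

#' Continuous-time random walk signal model
#'
#' `S(b) = S0 * E_alpha(-(b * D)^beta)` with `E_alpha` the one-parameter
#' Mittag-Leffler function; `alpha` and `beta` index temporal and spatial
#' diffusion heterogeneity. `alpha = 1` reduces to the stretched
#' exponential, `alpha = beta = 1` to the mono-exponential model.
#'
#' @param params a `ModelParamSet("CTRW", d = , alpha = , beta = )`.
#' @inheritParams memSignal
#' @return Modelled signal.
#' @export
ctrwSignal <- function(params, b) {
  p <- .sigParams(params, "CTRW")
  b <- .checkB(b)
  z <- -(b * p@params[["d"]] * .D_SCALE)^p@params[["beta"]]
  p@s0 * mittagLeffler(p@params[["alpha"]], z)
}

#' @rdname dwiSignal
#' @export
setMethod("dwiSignal", "ModelParamSet", function(params, b) {
  switch(params@family,
         MEM = memSignal(params, b),
         SEM = semSignal(params, b),
         IVIM = ivimSignal(params, b),
         DKI = dkiSignal(params, b),
         IVIM_DKI = ivimDkiSignal(params, b),
         CTRW = ctrwSignal(params, b),
         FROC = frocSignal(params, b))
})
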