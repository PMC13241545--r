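#' @include AllClasses.R signal-models.R utils.R
NULL

## Constrained nonlinear least-squares estimation of the seven model
## families from observed signal decays.

#' Observed signal decay
#'
#' One voxel's or ROI's signal intensities over a b-value scheme.
#'
#' @slot scheme a [BValueScheme-class].
#' @slot signal numeric vector of observed intensities (a.u.), positive,
#'   same length as the scheme.
#' @aliases SignalDecay-class
#' @export
setClass("SignalDecay",
         slots = c(scheme = "BValueScheme", signal = "numeric"))

setValidity("SignalDecay", function(object) {
  if (length(object@signal) != length(object@scheme@bvalues))
    return("signal and scheme lengths differ")
  if (anyNA(object@signal) || any(!is.finite(object@signal)))
    return("signal must be finite")
  if (any(object@signal <= 0))
    return("signal intensities must be positive")
  TRUE
})

#' Construct a signal decay
#'
#' @param scheme a [BValueScheme-class] (or numeric b-value vector).
#' @param signal observed intensities, same length.
#' @return A [SignalDecay-class].
#' @export
signalDecay <- function(scheme, signal) {
  if (is.numeric(scheme)) scheme <- bValueScheme(scheme)
  new("SignalDecay", scheme = scheme, signal = as.numeric(signal))
}

#' Fitting configuration
#'
#' Assembles bounds, b-value subset policy and optimizer settings for
#' [fitModel()] and [fitAllModels()].
#'
#' @param bounds named list of `c(low, high)` per parameter name
#'   (`adc`, `ddc`, `d`, `dstar`, `dp`, `f`, `alpha`, `beta`, `k`, `mu`),
#'   diffusivities in 1e-3 mm^2/s; entries override the defaults.
#' @param bSubset named list mapping family to the b-values used for that
#'   family; defaults: IVIM uses b <= 1000 (perfusion-sensitive range),
#'   DKI uses b <= `bMaxDki` (kurtosis validity), IVIM-DKI uses
#'   b <= `ivimDkiBMax`, all other families use the full scheme.
#' @param maxIter maximum optimizer iterations per start.
#' @param tol convergence tolerance on the relative RSS reduction.
#' @param ivimStrategy `"segmented"` (default, two-step perfusion/diffusion
#'   separation) or `"joint"` (all parameters at once).
#' @param bSplit IVIM segmentation threshold (default 200 s/mm^2).
#' @param nStarts number of multi-start points (default 5: one data-driven
#'   start plus Latin-hypercube draws over the bounds).
#' @param multistartSeed fixed seed for the Latin-hypercube starts, so
#'   fits are deterministic.
#' @param bMaxDki validity guard for the kurtosis expansion (s/mm^2).
#' @param ivimDkiBMax upper b-value used by the hybrid IVIM-DKI fit
#'   (default 2500 s/mm^2).
#' @param ivimDkiStrategy `"staged"` (default): tissue diffusivity and
#'   kurtosis are estimated on the perfusion-free range (b >= `bSplit`)
#'   and the perfusion fraction and pseudo-diffusion on the full range
#'   with the tissue pair fixed, alternating until stable; this breaks
#'   the strong f/K trade-off of the five-parameter joint fit.
#'   `"joint"` fits all parameters at once.
#' @param frocNoiseFloor when `TRUE` (default) the FROC model is fitted
#'   to squared magnitudes with a free noise-floor term, using the exact
#'   Rician second-moment identity `E[M^2] = S^2 + 2 sigma^2`; the FROC
#'   default b-range reaches deepest into the noise floor, where plain
#'   magnitude least squares biases D low.
#' @param frocMuRef reference value at which the FROC spatial constant
#'   `mu` is held during fitting. In the simplified b-value form only
#'   `beta` and the product `D * mu^(2 (beta - 1))` are identifiable
#'   from a single decay, so `mu` is profiled out at this documented
#'   reference (default 7.5, the centre of the range reported for
#'   prostate tissue) and flagged as convention-fixed; set to `NULL`
#'   for a free (vendor-like, ridge-degenerate) joint fit.
#' @return A list of class `fitConfig`.
#' @export
fitConfig <- function(bounds = list(), bSubset = list(), maxIter = 200L,
                      tol = 1e-10, ivimStrategy = c("segmented", "joint"),
                      bSplit = 200, nStarts = 5L,
                      multistartSeed = 20260923L, bMaxDki = 2000,
                      ivimDkiBMax = 2500, frocMuRef = 7.5,
                      ivimDkiStrategy = c("staged", "joint"),
                      frocNoiseFloor = TRUE) {
  def <- list(adc = c(0.05, 4), ddc = c(0.05, 4), d = c(0.05, 4),
              dstar = c(3, 100), dp = c(3, 100), f = c(0, 0.5),
              alpha = c(0.1, 1), beta = c(0.1, 1), k = c(0, 3),
              mu = c(1, 20))
  bounds <- modifyList(def, bounds)
  for (nm in names(bounds))
    if (!(length(bounds[[nm]]) == 2L && all(is.finite(bounds[[nm]])) &&
          bounds[[nm]][1] < bounds[[nm]][2]))
      stop("invalid bounds for '", nm, "'")
  structure(list(bounds = bounds, bSubset = bSubset, maxIter = as.integer(maxIter),
                 tol = tol, ivimStrategy = match.arg(ivimStrategy),
                 bSplit = bSplit, nStarts = as.integer(nStarts),
                 multistartSeed = as.integer(multistartSeed),
                 bMaxDki = bMaxDki, ivimDkiBMax = ivimDkiBMax,
                 frocMuRef = frocMuRef,
                 ivimDkiStrategy = match.arg(ivimDkiStrategy),
                 frocNoiseFloor = frocNoiseFloor),
            class = "fitConfig")
}

## b-values used for a family under the subset policy
.familySubset <- function(family, b, config) {
  if (!is.null(config$bSubset[[family]])) {
    keep <- b %in% config$bSubset[[family]]
  } else if (family == "IVIM") {
    keep <- b <= 1000
  } else if (family == "DKI") {
    keep <- b <= config$bMaxDki
  } else if (family == "IVIM_DKI") {
    ## the hybrid model needs extra high-b curvature to separate the
    ## kurtosis from the perfusion compartment; 2500 s/mm^2 is still
    ## well inside the expansion's validity (b << 3 / (D K)) for
    ## prostate parameter ranges
    keep <- b <= config$ivimDkiBMax
  } else {
    keep <- rep(TRUE, length(b))
  }
  keep
}

## forward model on the fitting parameter vector c(s0, <family params>)
.forward <- function(family, par, b) {
  s0 <- par[[1]]
  p <- par[-1]
  ps <- new("ModelParamSet", family = family, s0 = s0, params = p)
  as.numeric(dwiSignal(ps, b))
}

## deterministic Latin hypercube over [0,1]^d
.lhsUnit <- function(n, d) {
  sapply(seq_len(d), function(j) (sample(n) - runif(n)) / n)
}

## data-driven starting values per family
.heuristicStart <- function(family, b, s, bounds) {
  s0 <- max(s)
  ## crude ADC from the two extreme b-values
  i0 <- which.min(b); i1 <- which.max(b)
  adc0 <- if (b[i1] > b[i0])
    max((log(s[i0]) - log(s[i1])) / (b[i1] - b[i0]) / 1e-3, 0.1) else 1
  adc0 <- .clip(adc0, bounds$d[1], bounds$d[2])
  st <- switch(family,
    MEM = c(adc = adc0),
    SEM = c(ddc = adc0, alpha = 0.8),
    IVIM = c(d = adc0, dstar = 15, f = 0.15),
    DKI = c(d = min(adc0 * 1.2, bounds$d[2]), k = 0.8),
    IVIM_DKI = c(d = adc0, dp = 20, f = 0.15, k = 0.7),
    CTRW = c(d = min(adc0 * 1.1, bounds$d[2]), alpha = 0.9, beta = 0.8),
    FROC = c(d = min(adc0 * 1.1, bounds$d[2]), beta = 0.8, mu = 7.5))
  c(s0 = s0, st)
}

.boundsFor <- function(family, s, config) {
  nm <- .familyParams[[family]]
  lo <- c(s0 = 0.2 * max(s), vapply(nm, function(p) config$bounds[[p]][1], 1))
  hi <- c(s0 = 2.0 * max(s), vapply(nm, function(p) config$bounds[[p]][2], 1))
  names(lo) <- names(hi) <- c("s0", nm)
  list(lo = lo, hi = hi)
}

## single constrained Levenberg-Marquardt run; `fixed` holds parameters
## profiled out of the optimization (appended before forward evaluation).
## squared = TRUE fits in squared-magnitude space with a trailing
## noise-floor parameter c0 (Rician second moment: E[M^2] = S^2 + c0).
.nlsRun <- function(family, b, s, start, lo, hi, config, fixed = NULL,
                    squared = FALSE) {
  fn <- if (squared) {
    function(par) {
      n <- length(par)
      s^2 - .forward(family, c(par[-n], fixed), b)^2 - par[[n]]
    }
  } else {
    function(par) s - .forward(family, c(par, fixed), b)
  }
  res <- try(minpack.lm::nls.lm(
    par = pmin(pmax(start, lo), hi),
    lower = lo, upper = hi, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = config$maxIter, ftol = config$tol, ptol = 1e-12)),
    silent = TRUE)
  if (inherits(res, "try-error")) return(NULL)
  list(par = res$par, rss = sum(res$fvec^2), info = res$info,
       niter = res$niter, message = res$message)
}

## post-IVIM constraint: keep pseudo-diffusion above tissue diffusion
.fixPseudo <- function(family, par) {
  if (family == "IVIM" && par[["dstar"]] <= par[["d"]])
    par[["dstar"]] <- par[["d"]] + 1e-6
  if (family == "IVIM_DKI" && par[["dp"]] <= par[["d"]])
    par[["dp"]] <- par[["d"]] + 1e-6
  par
}

.mkFitResult <- function(family, par, rss, converged, niter, lo, hi,
                         message = "") {
  par <- .fixPseudo(family, par)
  tolb <- 1e-6 * (hi - lo)
  atb <- (par - lo < tolb) | (hi - par < tolb)
  ps <- new("ModelParamSet", family = family, s0 = unname(par[[1]]),
            params = par[-1])
  new("FitResult", params = ps, rss = rss, converged = converged,
      nIter = as.integer(niter), atBound = atb[-1],
      message = as.character(message))
}

#' Closed-form mono-exponential (ADC) fit
#'
#' Weighted linear regression of log-signal on b (weights proportional to
#' the squared signal, the usual first-order variance correction for
#' log-transformed data). A negative slope estimate is clipped to ADC = 0
#' and flagged `atBound`.
#'
#' @param decay a [SignalDecay-class] with at least two distinct b-values.
#' @return A [FitResult-class] for the MEM family (ADC in 1e-3 mm^2/s).
#' @export
#' @examples
#' d <- signalDecay(c(0, 1000), c(1, exp(-1)))
#' fitParams(fitMem(d))   # ADC = 1.0
fitMem <- function(decay) {
  stopifnot(is(decay, "SignalDecay"))
  b <- bValues(decay@scheme); s <- decay@signal
  if (length(unique(b)) < 2L) stop("fitMem needs >= 2 distinct b-values")
  fit <- lm(log(s) ~ b, weights = s^2)
  adc <- -unname(coef(fit)[2]) / 1e-3
  s0 <- exp(unname(coef(fit)[1]))
  atb <- adc <= 0
  adc <- max(adc, 0)
  resid <- s - s0 * exp(-b * adc * 1e-3)
  ps <- new("ModelParamSet", family = "MEM", s0 = s0, params = c(adc = adc))
  new("FitResult", params = ps, rss = sum(resid^2), converged = TRUE,
      nIter = 1L, atBound = c(adc = atb), message = "log-linear")
}

#' Fit one diffusion model by constrained nonlinear least squares
#'
#' Minimizes the residual sum of squares between the observed decay and
#' the family's forward signal over box constraints, using
#' Levenberg-Marquardt with multiple deterministic starting points (one
#' data-driven start plus seeded Latin-hypercube draws over the bounds).
#' Ties between starts are broken by lowest RSS, then lexicographically
#' smallest parameter vector, so results are reproducible bitwise.
#'
#' @param decay a [SignalDecay-class].
#' @param family one of [dwiModelFamilies()].
#' @param config a [fitConfig()].
#' @return A [FitResult-class]; `converged = FALSE` (never silent `NaN`)
#'   when no start converged.
#' @export
fitModel <- function(decay, family, config = fitConfig()) {
  stopifnot(is(decay, "SignalDecay"))
  family <- match.arg(family, dwiModelFamilies())
  if (family == "MEM") return(fitMem(decay))
  if (family == "IVIM" && config$ivimStrategy == "segmented")
    return(fitIvimSegmented(decay, config))
  if (family == "IVIM_DKI" && config$ivimDkiStrategy == "staged")
    return(fitIvimDkiStaged(decay, config))
  b <- bValues(decay@scheme); s <- decay@signal
  keep <- .familySubset(family, b, config)
  b <- b[keep]; s <- s[keep]
  nfree <- length(.familyParams[[family]]) + 1L
  if (length(b) < nfree + 1L)
    stop(family, " fit needs at least ", nfree + 1L, " b-values, got ",
         length(b))
  bd <- .boundsFor(family, s, config)
  ## FROC: mu is profiled out at its reference (ridge degeneracy)
  fixed <- NULL
  squared <- FALSE
  if (family == "FROC") {
    squared <- isTRUE(config$frocNoiseFloor)
    if (!is.null(config$frocMuRef)) {
      fixed <- c(mu = config$frocMuRef)
      bd$lo <- bd$lo[setdiff(names(bd$lo), "mu")]
      bd$hi <- bd$hi[setdiff(names(bd$hi), "mu")]
      nfree <- nfree - 1L
    }
  }
  starts <- list(.heuristicStart(family, b, s, config$bounds)[names(bd$lo)])
  if (config$nStarts > 1L) {
    u <- .withSeed(.deriveSeed(config$multistartSeed, family),
                   .lhsUnit(config$nStarts - 1L, nfree))
    for (i in seq_len(nrow(u)))
      starts[[i + 1L]] <- setNames(bd$lo + u[i, ] * (bd$hi - bd$lo),
                                   names(bd$lo))
  }
  if (squared) {
    ## trailing noise-floor parameter, started at a plausible SNR ~ 50
    bd$lo <- c(bd$lo, c0 = 0)
    bd$hi <- c(bd$hi, c0 = (0.5 * max(s))^2)
    starts <- lapply(starts, function(st)
      c(st, c0 = 2 * (max(s) / 50)^2))
  }
  best <- NULL
  for (st in starts) {
    r <- .nlsRun(family, b, s, st, bd$lo, bd$hi, config, fixed, squared)
    if (is.null(r)) next
    take <- if (is.null(best)) TRUE
            else if (r$rss < best$rss - 1e-12) TRUE
            else if (abs(r$rss - best$rss) <= 1e-12) {
              i <- which(r$par != best$par)[1]   # lexicographic tie-break
              !is.na(i) && r$par[[i]] < best$par[[i]]
            } else FALSE
    if (take) best <- r
  }
  if (is.null(best)) {
    ps <- new("ModelParamSet", family = family, s0 = max(s),
              params = .heuristicStart(family, b, s, config$bounds)[-1])
    return(new("FitResult", params = ps, rss = Inf, converged = FALSE,
               nIter = 0L, atBound = setNames(
                 rep(FALSE, length(.familyParams[[family]])),
                 .familyParams[[family]]),
               message = "no start converged"))
  }
  par <- best$par
  lo <- bd$lo; hi <- bd$hi
  if (squared) {
    par <- par[names(par) != "c0"]
    lo <- lo[names(lo) != "c0"]; hi <- hi[names(hi) != "c0"]
  }
  fr <- .mkFitResult(family, c(par, fixed), best$rss,
                     converged = best$info %in% 1:4, best$niter,
                     c(lo, fixed), c(hi, fixed), best$message)
  if (!is.null(fixed)) fr@atBound[names(fixed)] <- TRUE
  fr
}

#' Segmented IVIM fit
#'
#' Standard two-step perfusion/diffusion separation: (1) the tissue
#' diffusivity D is estimated mono-exponentially from b >= `bSplit`
#' (where the pseudo-diffusion compartment has decayed away); (2) with D
#' fixed, S0, f and D* are estimated on all b-values by constrained
#' nonlinear least squares. With fewer than three b-values above the
#' split the function falls back to the joint fit with a warning.
#'
#' @inheritParams fitModel
#' @return A [FitResult-class] for the IVIM family.
#' @export
fitIvimSegmented <- function(decay, config = fitConfig()) {
  stopifnot(is(decay, "SignalDecay"))
  b <- bValues(decay@scheme); s <- decay@signal
  keep <- .familySubset("IVIM", b, config)
  b <- b[keep]; s <- s[keep]
  hib <- b >= config$bSplit
  if (sum(hib) < 3L) {
    warning("fewer than 3 b-values above bSplit; falling back to joint IVIM fit")
    cfg <- config; cfg$ivimStrategy <- "joint"
    return(fitModel(decay, "IVIM", cfg))
  }
  if (sum(!hib) < 1L) stop("IVIM needs b-values below bSplit")
  ## step 1: tissue D from the diffusion-dominated range
  fit1 <- lm(log(s[hib]) ~ b[hib], weights = s[hib]^2)
  d <- .clip(-unname(coef(fit1)[2]) / 1e-3,
             config$bounds$d[1], config$bounds$d[2])
  sInt <- exp(unname(coef(fit1)[1]))        # extrapolated S0 * (1 - f)
  s0max <- max(s)
  f0 <- .clip(1 - sInt / s0max, config$bounds$f[1] + 1e-4,
              config$bounds$f[2])
  ## step 2: fix D, fit s0, f, D*
  lo <- c(s0 = 0.2 * s0max, f = config$bounds$f[1],
          dstar = max(config$bounds$dstar[1], d + 0.01))
  hi <- c(s0 = 2 * s0max, f = config$bounds$f[2],
          dstar = config$bounds$dstar[2])
  fn <- function(par) {
    s - par[[1]] * (par[[2]] * exp(-b * par[[3]] * 1e-3) +
                      (1 - par[[2]]) * exp(-b * d * 1e-3))
  }
  res <- minpack.lm::nls.lm(
    par = c(s0 = s0max, f = f0, dstar = 15),
    lower = lo, upper = hi, fn = fn,
    control = minpack.lm::nls.lm.control(maxiter = config$maxIter,
                                         ftol = config$tol, ptol = 1e-12))
  par <- c(s0 = unname(res$par[["s0"]]), d = d,
           dstar = unname(res$par[["dstar"]]), f = unname(res$par[["f"]]))
  lo2 <- c(s0 = lo[["s0"]], d = config$bounds$d[1], dstar = lo[["dstar"]],
           f = lo[["f"]])
  hi2 <- c(s0 = hi[["s0"]], d = config$bounds$d[2], dstar = hi[["dstar"]],
           f = hi[["f"]])
  ## joint polish from the segmented solution: removes the small D bias
  ## from residual perfusion signal above bSplit while keeping the
  ## deterministic segmented initialization
  pol <- .nlsRun("IVIM", b, s, par, lo2, hi2, config)
  if (!is.null(pol) && pol$rss <= sum(res$fvec^2) + 1e-15) {
    return(.mkFitResult("IVIM", pol$par, pol$rss, pol$info %in% 1:4,
                        res$niter + pol$niter, lo2, hi2, pol$message))
  }
  .mkFitResult("IVIM", par, sum(res$fvec^2), res$info %in% 1:4,
               res$niter, lo2, hi2, res$message)
}

#' Staged IVIM-DKI fit
#'
#' Alternating estimation for the five-parameter hybrid model: the
#' kurtosis tissue pair (D, K) is fitted on the perfusion-free range
#' (b >= `bSplit`, after subtracting the current perfusion estimate),
#' then the perfusion pair (f, Dp) with the tissue parameters fixed on
#' the configured IVIM-DKI range, for three alternations. This is the
#' hybrid-model analogue of segmented IVIM fitting and avoids the
#' strong f/K trade-off of the joint five-parameter problem.
#'
#' @inheritParams fitModel
#' @return A [FitResult-class] for the IVIM_DKI family.
#' @export
fitIvimDkiStaged <- function(decay, config = fitConfig()) {
  stopifnot(is(decay, "SignalDecay"))
  b <- bValues(decay@scheme); sig <- decay@signal
  keep <- .familySubset("IVIM_DKI", b, config)
  bb <- b[keep]; ss <- sig[keep]
  hi <- bb >= config$bSplit
  if (sum(hi) < 4L || sum(!hi) < 1L)
    stop("IVIM_DKI staged fit needs >= 4 b-values above bSplit and one below")
  perf <- 0
  s0m <- max(ss)
  r1 <- r2 <- NULL
  for (it in 1:3) {
    st <- pmax(ss - perf, 1e-6 * s0m)
    bd <- .boundsFor("DKI", st[hi], config)
    r1 <- minpack.lm::nls.lm(
      par = .heuristicStart("DKI", bb[hi], st[hi], config$bounds),
      lower = bd$lo, upper = bd$hi,
      fn = function(p)
        st[hi] - p[[1]] * exp(-bb[hi] * p[[2]] * 1e-3 +
                                bb[hi]^2 * (p[[2]] * 1e-3)^2 * p[[3]] / 6),
      control = minpack.lm::nls.lm.control(maxiter = config$maxIter,
                                           ftol = config$tol, ptol = 1e-12))
    d <- r1$par[[2]]; k <- r1$par[[3]]
    f0 <- .clip(1 - r1$par[[1]] / s0m, 1e-3, config$bounds$f[2])
    r2 <- minpack.lm::nls.lm(
      par = c(s0 = s0m, f = f0, dp = 20),
      lower = c(s0 = 0.2 * s0m, f = config$bounds$f[1],
                dp = max(config$bounds$dp[1], d + 0.01)),
      upper = c(s0 = 2 * s0m, f = config$bounds$f[2],
                dp = config$bounds$dp[2]),
      fn = function(p)
        ss - p[[1]] * (p[[2]] * exp(-bb * p[[3]] * 1e-3) +
                         (1 - p[[2]]) * exp(-bb * d * 1e-3 +
                                              bb^2 * (d * 1e-3)^2 * k / 6)),
      control = minpack.lm::nls.lm.control(maxiter = config$maxIter,
                                           ftol = config$tol, ptol = 1e-12))
    perf <- r2$par[[1]] * r2$par[[2]] * exp(-bb * r2$par[[3]] * 1e-3)
  }
  par <- c(s0 = unname(r2$par[["s0"]]), d = unname(r1$par[[2]]),
           dp = unname(r2$par[["dp"]]), f = unname(r2$par[["f"]]),
           k = unname(r1$par[[3]]))
  lo <- c(s0 = 0.2 * s0m, d = config$bounds$d[1], dp = config$bounds$dp[1],
          f = config$bounds$f[1], k = config$bounds$k[1])
  hi2 <- c(s0 = 2 * s0m, d = config$bounds$d[2], dp = config$bounds$dp[2],
           f = config$bounds$f[2], k = config$bounds$k[2])
  .mkFitResult("IVIM_DKI", par, sum(r2$fvec^2),
               r1$info %in% 1:4 && r2$info %in% 1:4,
               r1$niter + r2$niter, lo, hi2, r2$message)
}

#' Fit all seven models and assemble the 18-metric vector
#'
#' Runs every model family on its configured b-value subset and collects
#' the fitted parameters under their `ModelName_ParameterName` metric
#' names. Families whose validity requirements are not met by the scheme
#' (non-Gaussian families need a maximum b-value of at least 2000 s/mm^2;
#' every family needs more b-values than free parameters) or that fail to
#' converge are reported as missing (`NA`) with their flag set to
#' `FALSE`.
#'
#' @inheritParams fitModel
#' @return A list with elements `metrics` (named 18-vector, `NA` for
#'   unavailable families), `converged` (named logical per family) and
#'   `fits` (list of [FitResult-class] per converged family).
#' @export
fitAllModels <- function(decay, config = fitConfig()) {
  stopifnot(is(decay, "SignalDecay"))
  b <- bValues(decay@scheme)
  metrics <- setNames(rep(NA_real_, 18L), dwiMetricNames())
  conv <- setNames(logical(7L), dwiModelFamilies())
  fits <- list()
  nonGauss <- c("SEM", "DKI", "IVIM_DKI", "CTRW", "FROC")
  for (fam in dwiModelFamilies()) {
    bb <- b[.familySubset(fam, b, config)]
    if (fam %in% nonGauss && max(b) < 2000) {
      .audit("fit", family = fam, skipped = "max b < 2000")
      next
    }
    if (length(bb) < length(.familyParams[[fam]]) + 2L) {
      .audit("fit", family = fam, skipped = "too few b-values")
      next
    }
    res <- try(fitModel(decay, fam, config), silent = TRUE)
    if (inherits(res, "try-error")) {
      .audit("fit", family = fam, error = conditionMessage(attr(res, "condition")))
      next
    }
    conv[fam] <- res@converged
    if (res@converged) {
      metrics[names(paramMetrics(res@params))] <- paramMetrics(res@params)
      fits[[fam]] <- res
    }
  }
  list(metrics = metrics, converged = conv, fits = fits)
}

#' Aggregate voxel-level metrics over an ROI
#'
#' Reduces voxel-wise 18-metric vectors to a single lesion-level vector,
#' using only voxels whose fit converged for the given metric.
#'
#' @param voxelMetrics numeric matrix, voxels x metrics (columns named by
#'   [dwiMetricNames()] or any metric subset); `NA` marks non-converged
#'   voxels.
#' @param reducer summary function applied per metric (default `mean`).
#' @return A list with `metrics` (named vector) and `nVoxels` (named
#'   integer count of voxels contributing to each metric).
#' @export
roiAggregate <- function(voxelMetrics, reducer = mean) {
  voxelMetrics <- as.matrix(voxelMetrics)
  if (nrow(voxelMetrics) < 1L) stop("empty ROI")
  if (is.null(colnames(voxelMetrics))) stop("voxelMetrics must have metric names")
  vals <- apply(voxelMetrics, 2, function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else reducer(x)
  })
  n <- apply(voxelMetrics, 2, function(x) sum(is.finite(x)))
  list(metrics = vals, nVoxels = n)
}
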