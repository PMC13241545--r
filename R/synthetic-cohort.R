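## Synthetic cohort generator: clustered patients/lesions with zone,
## PI-RADS, grade-group and csPCa labels, group-calibrated diffusion
## metrics, Rician-noised signal decays, two-reader replicates and
## two-vendor batch effects. All randomness flows from one root seed via
## labelled sub-streams, so every artefact is reproducible.

#' Cohort generator configuration
#'
#' @param nPatients number of eligible patients (default 162).
#' @param nScreened number of screened patients before exclusions
#'   (default 245); used by [screeningSummary()] bookkeeping.
#' @param exclusions named integer vector of screening exclusions; the
#'   default 25 prior interventions + 15 acute prostatitis + 33 incomplete
#'   protocols + 10 severe artifacts reduces 245 screened to 162 eligible.
#' @param pMultiple probability that a patient carries more than one
#'   MRI-suspicious lesion (default 0.283).
#' @param multipleSizes probabilities of 2 or 3 lesions given a
#'   multi-lesion patient.
#' @param zoneMixPZ probability that a lesion lies in the peripheral zone
#'   (default 0.442).
#' @param cspcaPrevalence named per-zone csPCa lesion prevalence.
#' @param patientSd standard deviation of the patient-level random
#'   intercept on the csPCa logit scale (induces intra-patient
#'   correlation of lesion risk; default 0.5).
#' @param psadLog2OR odds ratio of csPCa per doubling of PSAD
#'   (default 2).
#' @param snr Rician signal-to-noise ratio at b = 0 for generated decays.
#' @param interMetricCorr rank correlation among the tissue-diffusivity
#'   metrics within a lesion (default 0.7; other metric pairs are
#'   conditionally independent).
#' @param effectMetrics `"all"` (every metric follows its group-specific
#'   calibration) or a character vector naming the metrics that carry the
#'   pathology signal; the remaining metrics are then drawn from the
#'   non-csPCa calibration for both groups (a "planted predictors"
#'   design for pipeline validation).
#' @param targetICC inter-reader intraclass correlation targeted by the
#'   default reader jitter (default 0.9).
#' @param vendor vendor/batch label of the generated cohort.
#' @param calibration metric calibration table ([metricCalibration()]).
#' @param clinical clinical calibration list ([clinicalCalibration()]).
#' @param seed root seed for all generator sub-streams.
#' @return List of class `cohortConfig`.
#' @export
cohortConfig <- function(nPatients = 162L, nScreened = 245L,
                         exclusions = c(prior_intervention = 25L,
                                        acute_prostatitis = 15L,
                                        incomplete_protocol = 33L,
                                        severe_artifacts = 10L),
                         pMultiple = 0.283,
                         multipleSizes = c("2" = 0.65, "3" = 0.35),
                         zoneMixPZ = 0.442,
                         cspcaPrevalence = c(PZ = 0.616, TZ = 0.368),
                         patientSd = 0.5, psadLog2OR = 2, snr = 50,
                         interMetricCorr = 0.7, effectMetrics = "all",
                         targetICC = 0.9, vendor = "vendorA",
                         calibration = metricCalibration(),
                         clinical = clinicalCalibration(),
                         seed = 20260101L) {
  stopifnot(nPatients >= 1L, pMultiple >= 0, pMultiple <= 1,
            abs(sum(multipleSizes) - 1) < 1e-8,
            zoneMixPZ >= 0, zoneMixPZ <= 1,
            all(cspcaPrevalence >= 0 & cspcaPrevalence <= 1),
            patientSd >= 0, snr > 0,
            interMetricCorr > -1, interMetricCorr < 1,
            targetICC > 0, targetICC <= 1)
  for (tb in clinical$pirads_given_cspca)
    if (abs(sum(tb) - 1) > 1e-8) stop("pirads_given_cspca rows must sum to 1")
  for (tb in clinical$gg_given_cspca)
    if (abs(sum(tb) - 1) > 1e-8) stop("gg_given_cspca rows must sum to 1")
  if (!identical(effectMetrics, "all")) {
    bad <- setdiff(effectMetrics, dwiMetricNames())
    if (length(bad)) stop("unknown effect metrics: ", paste(bad, collapse = ", "))
  }
  structure(as.list(environment()), class = "cohortConfig")
}

#' Screening and exclusion bookkeeping
#'
#' @param config a [cohortConfig()].
#' @return data.frame with screened count, each exclusion category, and
#'   the eligible patient count (screened minus exclusions).
#' @export
#' @examples
#' screeningSummary(cohortConfig())   # 245 screened -> 162 eligible
screeningSummary <- function(config = cohortConfig()) {
  elig <- config$nScreened - sum(config$exclusions)
  data.frame(stage = c("screened", names(config$exclusions), "eligible"),
             n = c(config$nScreened, -as.integer(config$exclusions), elig))
}

## latent-normal correlation reproducing a target Spearman rho
.pearsonFromSpearman <- function(rho) 2 * sin(pi * rho / 6)

## quantile functions per metric for one group x zone
.metricQuantiles <- function(calibration, group, zone) {
  rows <- calibration[calibration$group == group & calibration$zone == zone, ]
  if (nrow(rows) != 18L)
    stop("unknown group/zone: ", group, "/", zone)
  qs <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    if (r$metric %in% .boundedMetrics)
      .quantileFun(.logitnormFromQuartiles(r$median, r$q1, r$q3))
    else
      .quantileFun(.lnormFromQuartiles(r$median, r$q1, r$q3))
  })
  names(qs) <- rows$metric
  qs[dwiMetricNames()]
}

#' Draw lesion-level diffusion parameters for one pathology group
#'
#' Draws 18-metric vectors from the group- and zone-specific calibrated
#' distributions (log-normal for positive metrics, logit-normal for
#' bounded shape metrics), coupled through a Gaussian copula that gives
#' the tissue-diffusivity metrics a common rank correlation.
#'
#' @param group `"csPCa"` or `"non-csPCa"`.
#' @param zone `"PZ"` or `"TZ"`.
#' @param n number of lesions to draw.
#' @param seed integer seed.
#' @param config a [cohortConfig()] providing calibration, correlation
#'   and the planted-effect metric set.
#' @return Numeric matrix `n` x 18 with columns [dwiMetricNames()].
#' @export
#' @examples
#' m <- drawLesionParams("csPCa", "PZ", n = 5, seed = 1)
#' m[, "MEM_ADC"]
drawLesionParams <- function(group = c("csPCa", "non-csPCa"),
                             zone = c("PZ", "TZ"), n = 1L, seed = 1L,
                             config = cohortConfig()) {
  group <- match.arg(group); zone <- match.arg(zone)
  qs <- .metricQuantiles(config$calibration, group, zone)
  if (!identical(config$effectMetrics, "all") && group == "csPCa") {
    null.qs <- .metricQuantiles(config$calibration, "non-csPCa", zone)
    keep <- intersect(config$effectMetrics, dwiMetricNames())
    for (m in setdiff(dwiMetricNames(), keep)) qs[[m]] <- null.qs[[m]]
  }
  mets <- dwiMetricNames()
  R <- diag(18)
  dimnames(R) <- list(mets, mets)
  r <- .pearsonFromSpearman(config$interMetricCorr)
  for (a in .dTypeMetrics) for (b in .dTypeMetrics)
    if (a != b) R[a, b] <- r
  if (!identical(config$effectMetrics, "all")) {
    ## planted-predictor design: the null metrics are pure noise, so the
    ## copula must not leak outcome signal from planted into null
    ## metrics via the diffusivity block
    eff <- intersect(config$effectMetrics, mets)
    nul <- setdiff(mets, eff)
    R[eff, nul] <- 0
    R[nul, eff] <- 0
  }
  L <- chol(R)
  z <- .withSeed(seed, matrix(rnorm(n * 18L), n, 18L)) %*% L
  u <- pnorm(z)
  out <- sapply(seq_along(mets), function(j) qs[[mets[j]]](u[, j]))
  out <- matrix(out, nrow = n, dimnames = list(NULL, mets))
  out
}

#' Simulate a Rician-noised signal decay
#'
#' Magnitude-MRI noise model: the noiseless forward signal is perturbed
#' by independent Gaussian noise of standard deviation `s0 / snr` in both
#' quadrature channels and the magnitude is taken, i.e.
#' `|S(b) + e1 + i e2|`.
#'
#' @param params a [ModelParamSet-class] (any family).
#' @param scheme a [BValueScheme-class].
#' @param snr signal-to-noise ratio at b = 0; `Inf` gives the exact
#'   forward signal.
#' @param seed integer seed.
#' @return A [SignalDecay-class].
#' @export
generateDecay <- function(params, scheme = defaultBScheme(), snr = 50,
                          seed = 1L) {
  stopifnot(is(params, "ModelParamSet"), snr > 0)
  s <- as.numeric(dwiSignal(params, bValues(scheme)))
  if (is.finite(snr)) {
    sd <- params@s0 / snr
    e <- .withSeed(seed, matrix(rnorm(2L * length(s), sd = sd), ncol = 2L))
    s <- sqrt((s + e[, 1])^2 + e[, 2]^2)
  }
  signalDecay(scheme, s)
}

#' Reader measurement-error specification
#'
#' @param multSd per-reader multiplicative jitter standard deviation
#'   (scalar or named per metric).
#' @param addSd per-reader additive jitter standard deviation in metric
#'   units (scalar or named per metric).
#' @return List of class `readerEffect`.
#' @export
readerEffect <- function(multSd = 0, addSd = 0) {
  stopifnot(all(multSd >= 0), all(addSd >= 0))
  structure(list(multSd = multSd, addSd = addSd), class = "readerEffect")
}

#' Reader jitter targeting a given ICC
#'
#' Uses the variance-components identity `ICC = var_b / (var_b + var_e)`:
#' given the between-lesion variance of each metric, the additive jitter
#' standard deviation `sqrt(var_b * (1/ICC - 1))` yields the target
#' intraclass correlation.
#'
#' @param truth lesion-by-metric matrix of true values.
#' @param targetICC desired two-way single-rater ICC.
#' @return A [readerEffect()] with per-metric additive jitter.
#' @export
readerEffectForICC <- function(truth, targetICC = 0.9) {
  vb <- apply(truth, 2, var)
  readerEffect(addSd = sqrt(vb * (1 / targetICC - 1)))
}

.effectSd <- function(x, metric, values) {
  if (length(x) == 1L && is.null(names(x))) return(rep(x, length(values)))
  if (!metric %in% names(x)) return(rep(0, length(values)))
  rep(unname(x[[metric]]), length(values))
}

#' Simulate two readers' measurements
#'
#' Produces two noisy replicates of each lesion-metric value under a
#' [readerEffect()]: `reader = truth * (1 + m) + a` with independent
#' Gaussian jitters per reader.
#'
#' @param truth lesion-by-metric numeric matrix.
#' @param effect a [readerEffect()].
#' @param seed integer seed.
#' @return List with matrices `reader1` and `reader2`.
#' @export
simulateTwoReaders <- function(truth, effect = readerEffect(), seed = 1L) {
  stopifnot(inherits(effect, "readerEffect"))
  truth <- as.matrix(truth)
  draws <- .withSeed(seed, list(
    m1 = matrix(rnorm(length(truth)), nrow(truth)),
    a1 = matrix(rnorm(length(truth)), nrow(truth)),
    m2 = matrix(rnorm(length(truth)), nrow(truth)),
    a2 = matrix(rnorm(length(truth)), nrow(truth))))
  mk <- function(m, a) {
    out <- truth
    for (j in seq_len(ncol(truth))) {
      met <- colnames(truth)[j]
      ms <- .effectSd(effect$multSd, met, truth[, j])
      as <- .effectSd(effect$addSd, met, truth[, j])
      out[, j] <- truth[, j] * (1 + m[, j] * ms) + a[, j] * as
    }
    out
  }
  list(reader1 = mk(draws$m1, draws$a1), reader2 = mk(draws$m2, draws$a2))
}

#' Vendor (scanner) batch-effect specification
#'
#' A location-scale perturbation `metric * scale + shift` applied to the
#' measurements of one batch, emulating non-biological scanner effects.
#'
#' @param batch batch label the effect applies to.
#' @param shift additive shift (scalar or named per metric, metric units).
#' @param scale multiplicative scale (scalar or named per metric, > 0).
#' @return List of class `vendorEffect`.
#' @export
vendorEffect <- function(batch, shift = 0, scale = 1) {
  stopifnot(all(scale > 0))
  structure(list(batch = batch, shift = shift, scale = scale),
            class = "vendorEffect")
}

#' Apply a vendor batch effect to a cohort
#'
#' Rescales and shifts the measurement assays (`reader1`, `reader2`,
#' `measured` - ground truth is left untouched) of all lesions whose
#' `vendor` label matches the effect's batch.
#'
#' @param cohort a [DiffusionCohort-class].
#' @param effect a [vendorEffect()].
#' @return The modified [DiffusionCohort-class].
#' @export
applyVendorEffect <- function(cohort, effect) {
  stopifnot(is(cohort, "DiffusionCohort"), inherits(effect, "vendorEffect"))
  nm <- names(effect$shift)
  if (!is.null(nm) && length(bad <- setdiff(nm, dwiMetricNames())))
    stop("unknown metric in vendor shift: ", paste(bad, collapse = ", "))
  nm <- names(effect$scale)
  if (!is.null(nm) && length(bad <- setdiff(nm, dwiMetricNames())))
    stop("unknown metric in vendor scale: ", paste(bad, collapse = ", "))
  sel <- lesionData(cohort)$vendor == effect$batch
  if (!any(sel)) return(cohort)
  getv <- function(x, metric, default) {
    if (length(x) == 1L && is.null(names(x))) return(x)
    if (metric %in% names(x)) unname(x[[metric]]) else default
  }
  for (a in intersect(c("reader1", "reader2", "measured"),
                      SummarizedExperiment::assayNames(cohort))) {
    m <- SummarizedExperiment::assay(cohort, a)
    for (met in rownames(m))
      m[met, sel] <- m[met, sel] * getv(effect$scale, met, 1) +
        getv(effect$shift, met, 0)
    SummarizedExperiment::assay(cohort, a) <- m
  }
  cohort
}

## truncated-normal age draw by inverse cdf
.drawAge <- function(n, cal) {
  sd <- (cal$q3 - cal$q1) / (2 * .Z75)
  plo <- pnorm(cal$lo, cal$median, sd); phi <- pnorm(cal$hi, cal$median, sd)
  qnorm(runif(n, plo, phi), cal$median, sd)
}

.drawLnorm <- function(n, cal) {
  p <- .lnormFromQuartiles(cal$median, cal$q1, cal$q3)
  rlnorm(n, p$mu, p$sigma)
}

#' Generate a clustered synthetic cohort
#'
#' Builds a full lesion-level cohort with the structure the downstream
#' analysis assumes: patients carry one or more lesions (sharing their
#' clinical covariates and a patient-level random intercept of lesion
#' risk), lesions carry zone, PI-RADS, grade-group and csPCa labels and
#' group-calibrated true diffusion metrics, and two reader replicates
#' plus their average are simulated per lesion.
#'
#' @param config a [cohortConfig()].
#' @return A [DiffusionCohort-class] with assays `truth`, `reader1`,
#'   `reader2` and `measured`.
#' @export
#' @examples
#' coh <- generateCohort(cohortConfig(nPatients = 20, seed = 7))
#' coh
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "cohortConfig"))
  cal <- config$clinical
  seed <- config$seed
  np <- config$nPatients

  pat <- .withSeed(.deriveSeed(seed, "patients"), {
    data.frame(
      patient_id = sprintf("P%03d", seq_len(np)),
      age = .drawAge(np, cal$age),
      psa = .drawLnorm(np, cal$psa),
      prostate_volume = .drawLnorm(np, cal$prostate_volume),
      dre = rbinom(np, 1L, cal$dre_positive),
      u = rnorm(np, 0, config$patientSd),
      nLesions = {
        multi <- runif(np) < config$pMultiple
        sz <- 1L + as.integer(multi)
        extra <- runif(np) < config$multipleSizes[["3"]] /
          sum(config$multipleSizes)
        sz + as.integer(multi & extra)
      })
  })
  pat$psad <- pat$psa / pat$prostate_volume

  idx <- rep(seq_len(np), pat$nLesions)
  nl <- length(idx)
  les <- pat[idx, c("patient_id", "age", "psa", "prostate_volume",
                    "dre", "psad", "u")]
  les$lesion_id <- sprintf("L%04d", seq_len(nl))

  les <- .withSeed(.deriveSeed(seed, "lesions"), {
    les$zone <- ifelse(runif(nl) < config$zoneMixPZ, "PZ", "TZ")
    eta <- qlogis(config$cspcaPrevalence[les$zone]) +
      log(config$psadLog2OR) * log2(les$psad / cal$psa$median *
                                      cal$prostate_volume$median) +
      les$u
    les$cspca <- as.integer(runif(nl) < plogis(eta))
    grp <- ifelse(les$cspca == 1L, "csPCa", "non-csPCa")
    les$gg <- vapply(grp, function(g) {
      tb <- cal$gg_given_cspca[[g]]
      as.integer(sample(names(tb), 1L, prob = tb))
    }, integer(1))
    les$pirads <- vapply(grp, function(g) {
      tb <- cal$pirads_given_cspca[[g]]
      as.integer(sample(names(tb), 1L, prob = tb))
    }, integer(1))
    les$diameter <- NA_real_
    les$volume <- NA_real_
    for (g in c("csPCa", "non-csPCa")) {
      sel <- grp == g
      les$diameter[sel] <- pmax(.drawLnorm(sum(sel), cal$diameter[[g]]), 0.3)
      les$volume[sel] <- .drawLnorm(sum(sel), cal$volume[[g]])
    }
    les
  })
  les$vendor <- config$vendor

  ## true diffusion metrics per pathology x zone stratum
  truth <- matrix(NA_real_, nl, 18L, dimnames = list(NULL, dwiMetricNames()))
  grp <- ifelse(les$cspca == 1L, "csPCa", "non-csPCa")
  for (g in c("csPCa", "non-csPCa")) for (z in c("PZ", "TZ")) {
    sel <- grp == g & les$zone == z
    if (!any(sel)) next
    truth[sel, ] <- drawLesionParams(
      g, z, n = sum(sel),
      seed = .deriveSeed(seed, paste0("metrics:", g, ":", z)),
      config = config)
  }

  eff <- readerEffectForICC(truth, config$targetICC)
  rd <- simulateTwoReaders(truth, eff, seed = .deriveSeed(seed, "readers"))
  measured <- (rd$reader1 + rd$reader2) / 2

  rownames(les) <- NULL
  keep <- c("lesion_id", "patient_id", "age", "psa", "psad",
            "prostate_volume", "dre", "zone", "pirads", "gg", "cspca",
            "diameter", "volume", "vendor")
  DiffusionCohort(les[, keep],
                  truth = t(truth), reader1 = t(rd$reader1),
                  reader2 = t(rd$reader2), measured = t(measured),
                  metadata = list(config = config, seed = seed))
}
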