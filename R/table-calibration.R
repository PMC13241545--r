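## Default calibration of the synthetic cohort generator: group- and
## zone-specific median (quartile) summaries for the 18 diffusion metrics
## and the clinical covariates, representative of 3T prostate
## multi-b-value DWI in csPCa versus non-csPCa lesions of the peripheral
## (PZ) and transition (TZ) zones. Positive unbounded metrics are drawn
## log-normally, (0,1)-bounded shape metrics logit-normally, each
## parameterized by inverting the median/IQR summary.

.calRow <- function(metric, group, zone, m, q1, q3) {
  data.frame(metric = metric, group = group, zone = zone,
             median = m, q1 = q1, q3 = q3, stringsAsFactors = FALSE)
}

#' Default per-group metric calibration
#'
#' Median and interquartile summaries of each diffusion metric for the
#' four pathology-by-zone groups (csPCa/non-csPCa in PZ/TZ) used as the
#' generator's default lesion parameter distributions. Diffusivities in
#' 1e-3 mm^2/s. csPCa lesions have lower diffusivities, lower CTRW_alpha
#' and higher kurtosis than non-csPCa lesions, with zone-specific detail.
#'
#' @return data.frame with columns `metric`, `group` (`csPCa` or
#'   `non-csPCa`), `zone`, `median`, `q1`, `q3`.
#' @export
metricCalibration <- function() {
  ## metric, csPCa-PZ, non-PZ, csPCa-TZ, non-TZ; each c(median, q1, q3)
  tab <- list(
    "MEM_ADC"     = list(c(0.88, 0.76, 0.96), c(1.11, 1.00, 1.22),
                         c(0.84, 0.80, 0.97), c(1.11, 1.04, 1.18)),
    "SEM_DDC"     = list(c(1.07, 0.89, 1.27), c(1.42, 1.22, 1.54),
                         c(0.99, 0.90, 1.12), c(1.36, 1.29, 1.47)),
    "SEM_alpha"   = list(c(0.68, 0.64, 0.70), c(0.71, 0.67, 0.74),
                         c(0.69, 0.66, 0.71), c(0.70, 0.67, 0.73)),
    "IVIM_D"      = list(c(0.80, 0.71, 0.91), c(1.04, 0.93, 1.14),
                         c(0.81, 0.74, 0.89), c(1.03, 0.94, 1.09)),
    "IVIM_Dstar"  = list(c(13.41, 11.07, 15.95), c(14.40, 11.89, 18.45),
                         c(13.52, 11.19, 15.75), c(15.10, 12.48, 18.93)),
    "IVIM_f"      = list(c(0.17, 0.14, 0.20), c(0.18, 0.15, 0.21),
                         c(0.16, 0.14, 0.18), c(0.20, 0.17, 0.23)),
    "DKI_D"       = list(c(1.20, 1.01, 1.37), c(1.53, 1.34, 1.62),
                         c(1.14, 1.07, 1.24), c(1.51, 1.44, 1.62)),
    "DKI_K"       = list(c(0.72, 0.65, 0.80), c(0.62, 0.55, 0.66),
                         c(0.74, 0.68, 0.81), c(0.64, 0.61, 0.69)),
    "IVIM-DKI_D"  = list(c(0.93, 0.82, 1.10), c(1.25, 1.10, 1.33),
                         c(0.91, 0.85, 1.07), c(1.24, 1.14, 1.32)),
    "IVIM-DKI_Dp" = list(c(20.56, 18.51, 23.15), c(19.61, 16.10, 22.24),
                         c(21.65, 19.20, 24.14), c(21.85, 19.57, 24.37)),
    "IVIM-DKI_f"  = list(c(0.19, 0.17, 0.22), c(0.21, 0.18, 0.22),
                         c(0.17, 0.16, 0.20), c(0.18, 0.17, 0.21)),
    "IVIM-DKI_K"  = list(c(0.56, 0.50, 0.65), c(0.50, 0.44, 0.57),
                         c(0.60, 0.53, 0.67), c(0.56, 0.51, 0.60)),
    "CTRW_D"      = list(c(1.02, 0.90, 1.18), c(1.31, 1.15, 1.42),
                         c(0.98, 0.92, 1.14), c(1.30, 1.23, 1.38)),
    "CTRW_alpha"  = list(c(0.84, 0.79, 0.89), c(0.90, 0.88, 0.93),
                         c(0.82, 0.79, 0.88), c(0.92, 0.90, 0.94)),
    "CTRW_beta"   = list(c(0.76, 0.72, 0.80), c(0.77, 0.73, 0.81),
                         c(0.77, 0.73, 0.80), c(0.75, 0.71, 0.79)),
    "FROC_D"      = list(c(1.03, 0.88, 1.18), c(1.30, 1.15, 1.40),
                         c(1.01, 0.92, 1.07), c(1.29, 1.23, 1.37)),
    "FROC_beta"   = list(c(0.75, 0.71, 0.78), c(0.77, 0.75, 0.80),
                         c(0.74, 0.72, 0.76), c(0.74, 0.71, 0.78)),
    "FROC_mu"     = list(c(7.40, 7.22, 7.62), c(7.59, 7.45, 7.78),
                         c(7.39, 7.24, 7.56), c(7.66, 7.49, 7.80)))
  grp <- c("csPCa", "non-csPCa", "csPCa", "non-csPCa")
  zon <- c("PZ", "PZ", "TZ", "TZ")
  out <- do.call(rbind, lapply(names(tab), function(m) {
    do.call(rbind, lapply(1:4, function(i) {
      v <- tab[[m]][[i]]
      .calRow(m, grp[i], zon[i], v[1], v[2], v[3])
    }))
  }))
  rownames(out) <- NULL
  out
}

## metrics drawn logit-normally on (0, 1)
.boundedMetrics <- c("SEM_alpha", "IVIM_f", "IVIM-DKI_f", "CTRW_alpha",
                     "CTRW_beta", "FROC_beta")

## the correlated tissue-diffusivity block
.dTypeMetrics <- c("MEM_ADC", "SEM_DDC", "IVIM_D", "DKI_D", "IVIM-DKI_D",
                   "CTRW_D", "FROC_D")

#' Default clinical covariate calibration
#'
#' Patient-level marginals (median and quartiles, or a proportion) used
#' by the generator: age in years, serum PSA in ng/mL, prostate volume in
#' mL (PSAD is their ratio, ng/mL^2), positive-DRE fraction, and
#' group-specific lesion diameter (cm) and volume (cm^3).
#'
#' @return Named list of calibration entries.
#' @export
clinicalCalibration <- function() {
  list(
    age = list(median = 67, q1 = 62, q3 = 73, dist = "normal",
               lo = 45, hi = 92),
    psa = list(median = 13.27, q1 = 8.34, q3 = 23.21, dist = "lnorm"),
    prostate_volume = list(median = 45.61, q1 = 30.79, q3 = 63.15,
                           dist = "lnorm"),
    dre_positive = 0.487,
    diameter = list(
      "csPCa"     = list(median = 2.38, q1 = 1.57, q3 = 3.28),
      "non-csPCa" = list(median = 1.61, q1 = 1.34, q3 = 2.12)),
    volume = list(
      "csPCa"     = list(median = 2.94, q1 = 0.93, q3 = 6.46),
      "non-csPCa" = list(median = 1.10, q1 = 0.68, q3 = 2.04)),
    ## conditional label tables
    pirads_given_cspca = list(
      "csPCa"     = c("3" = 24 / 107, "4" = 36 / 107, "5" = 47 / 107),
      "non-csPCa" = c("3" = 100 / 117, "4" = 12 / 117, "5" = 5 / 117)),
    gg_given_cspca = list(
      "csPCa"     = c("2" = 37 / 107, "3" = 32 / 107, "4" = 15 / 107,
                      "5" = 23 / 107),
      "non-csPCa" = c("0" = 88 / 117, "1" = 29 / 117)))
}
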