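## Bootstrap-LASSO stability selection of diffusion metrics.

#' Bootstrap-LASSO stability selection
#'
#' In each bootstrap resample, lesions are drawn by resampling whole
#' patients with replacement (preserving the clustered structure;
#' lesion-level resampling is available via `unit`), metrics are
#' z-scored within the resample, an L1-penalized logistic model for the
#' csPCa outcome is fitted along its regularization path, the penalty is
#' chosen by five-fold cross-validation (lambda of minimal mean CV
#' deviance), and the metrics with non-zero coefficients are recorded.
#' Metrics selected in more than `freqThreshold` of the resamples form
#' the stable set. Resamples degenerate to a single outcome class are
#' redrawn and counted.
#'
#' @param cohort cohort or lesion table (typically the training split).
#' @param metrics candidate metric names (e.g. the ICC-gated set).
#' @param outcome binary outcome column (default `"cspca"`).
#' @param nBoot number of bootstrap resamples (default 500).
#' @param freqThreshold stability frequency threshold (default 0.5).
#' @param unit resampling unit, `"patient"` (default) or `"lesion"`.
#' @param seed integer seed; the whole procedure is deterministic given
#'   the seed.
#' @return A [StabilityResult-class].
#' @export
bootstrapLassoSelect <- function(cohort, metrics = NULL, outcome = "cspca",
                                 nBoot = 500L, freqThreshold = 0.5,
                                 unit = c("patient", "lesion"),
                                 seed = 1L) {
  unit <- match.arg(unit)
  df <- .tbl(cohort)
  if (is.null(metrics))
    metrics <- intersect(dwiMetricNames(), colnames(df))
  stopifnot(length(metrics) >= 1L, all(metrics %in% colnames(df)))
  y <- df[[outcome]]
  stopifnot(all(y %in% 0:1))
  X <- as.matrix(df[, metrics, drop = FALSE])
  if (anyNA(X)) stop("missing metric values; exclude incomplete lesions first")
  pts <- as.character(df$patient_id)
  upts <- unique(pts)
  byPatient <- split(seq_len(nrow(df)), pts)

  counts <- setNames(numeric(length(metrics)), metrics)
  lambdas <- numeric(nBoot)
  nRedrawn <- 0L
  .withSeed(.deriveSeed(seed, "bootlasso"), {
    for (b in seq_len(nBoot)) {
      repeat {
        if (unit == "patient") {
          drawn <- sample(upts, length(upts), replace = TRUE)
          idx <- unlist(byPatient[drawn], use.names = FALSE)
        } else {
          drawn <- sample(nrow(df), nrow(df), replace = TRUE)
          idx <- drawn
        }
        if (length(unique(y[idx])) == 2L) break
        nRedrawn <- nRedrawn + 1L
      }
      Xb <- scale(X[idx, , drop = FALSE])
      sdz <- attr(Xb, "scaled:scale") == 0
      if (any(sdz)) Xb[, sdz] <- 0          # constant metric in resample
      yb <- y[idx]
      ## cluster-aware CV folds: every bootstrap copy of a sampling unit
      ## stays in one fold, otherwise duplicated lesions straddle folds,
      ## the CV curve is optimistically biased at small lambda and
      ## lambda.min grossly overselects
      ufold <- setNames(sample(rep_len(1:5, length(unique(drawn)))),
                        unique(drawn))
      foldid <- if (unit == "patient")
        rep(unname(ufold[drawn]), times = lengths(byPatient[drawn]))
      else unname(ufold[as.character(drawn)])
      cv <- glmnet::cv.glmnet(Xb, yb, family = "binomial",
                              foldid = foldid, standardize = FALSE,
                              type.measure = "deviance")
      lambdas[b] <- cv$lambda.min
      co <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
      counts[names(co)[co != 0]] <- counts[names(co)[co != 0]] + 1
    }
  })
  freq <- counts / nBoot
  if (nRedrawn > 0L)
    .audit("bootlasso", redrawn_degenerate_resamples = nRedrawn)
  new("StabilityResult", frequencies = freq,
      stableSet = names(freq)[freq > freqThreshold],
      threshold = freqThreshold, nBoot = as.integer(nBoot),
      lambdas = lambdas, nRedrawn = nRedrawn)
}
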