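## Nested logistic risk models, ROC evaluation, DeLong comparison and
## decision-curve analysis.

.CLINICAL_COVARIATES <- c("age", "psad", "dre", "zone", "volume", "pirads")

.fitLogistic <- function(df, covariates, outcome = "cspca") {
  X <- .designMatrix(df, covariates)
  y <- as.numeric(df[[outcome]])
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  co <- coef(fit)
  if (anyNA(co) || any(abs(co[-1]) > 20)) {
    ## separation or collinearity: light ridge fallback keeps the model
    ## usable; flagged to the caller
    warning("possible separation; refitting with a small ridge penalty")
    g <- glmnet::glmnet(X[, -1, drop = FALSE], y, family = "binomial",
                        alpha = 0, lambda = 1e-2, standardize = TRUE)
    co <- c(as.numeric(g$a0), as.numeric(g$beta))
    names(co) <- colnames(X)
  }
  list(coef = co, covariates = covariates)
}

.predictLogistic <- function(model, df) {
  X <- .designMatrix(df, model$covariates)
  miss <- setdiff(names(model$coef), colnames(X))
  if (length(miss)) stop("missing covariate columns: ",
                         paste(miss, collapse = ", "))
  p <- as.numeric(plogis(X[, names(model$coef), drop = FALSE] %*% model$coef))
  ## keep probabilities strictly inside (0, 1): plogis saturates in
  ## double precision for extreme linear predictors
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

## deterministic Youden threshold: maximal sens + spec - 1, smallest
## threshold among ties; candidates are midpoints between adjacent scores
.youdenThreshold <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- if (length(s) > 1L) (head(s, -1) + s[-1]) / 2 else s
  cand <- c(min(s) - 1e-9, cand)
  J <- vapply(cand, function(t) {
    pred <- scores >= t
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(J)]
}

#' ROC-based evaluation of a risk score
#'
#' AUC by the Mann-Whitney (trapezoidal) estimator with a confidence
#' interval (stratified bootstrap by default, DeLong optionally), plus
#' the confusion-matrix rates at an operating threshold. The threshold
#' defaults to Youden's J maximizer on the supplied scores; pass the
#' training threshold explicitly when evaluating test or external data,
#' so the operating point is frozen at training time.
#'
#' @param scores numeric risk scores (higher = more suspicious).
#' @param labels binary outcome labels (0/1), both classes present.
#' @param threshold operating threshold; `NULL` derives it from these
#'   scores by Youden's J.
#' @param ciMethod `"bootstrap"` (stratified, `nBootCI` replicates) or
#'   `"delong"`.
#' @param nBootCI bootstrap replicates for the AUC CI (default 2000).
#' @param seed seed for the bootstrap CI.
#' @return A [ModelEval-class].
#' @export
rocMetrics <- function(scores, labels, threshold = NULL,
                       ciMethod = c("bootstrap", "delong"),
                       nBootCI = 2000L, seed = 1L) {
  ciMethod <- match.arg(ciMethod)
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L) stop("both outcome classes required")
  r <- pROC::roc(labels, scores, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  auc <- as.numeric(pROC::auc(r))
  ci <- if (ciMethod == "bootstrap")
    .withSeed(seed, as.numeric(pROC::ci.auc(r, method = "bootstrap",
                                            boot.n = nBootCI,
                                            boot.stratified = TRUE,
                                            progress = "none")))
  else as.numeric(pROC::ci.auc(r, method = "delong"))
  if (is.null(threshold)) threshold <- .youdenThreshold(scores, labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0); fn <- sum(!pred & labels == 1)
  new("ModelEval",
      auc = auc, aucCI = ci[c(1, 3)],
      accuracy = (tp + tn) / length(labels),
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
      threshold = threshold, n = length(labels),
      prevalence = mean(labels))
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the same lesions
#' using the DeLong structural-components covariance (midrank ties).
#'
#' @param scoresA,scoresB paired score vectors on identical lesions.
#' @param labels binary outcome labels.
#' @return List with `auc_diff` (AUC A minus AUC B) and `p` (two-sided).
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("DeLong test requires paired scores on identical lesions")
  labels <- as.numeric(labels)
  rA <- pROC::roc(labels, scoresA, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  rB <- pROC::roc(labels, scoresB, quiet = TRUE, direction = "<",
                  levels = c(0, 1))
  if (isTRUE(all.equal(scoresA, scoresB)))
    return(list(auc_diff = 0, p = 1))
  tst <- pROC::roc.test(rA, rB, method = "delong", paired = TRUE)
  list(auc_diff = as.numeric(pROC::auc(rA)) - as.numeric(pROC::auc(rB)),
       p = tst$p.value)
}

#' Fit the three nested clinical/diffusion risk models
#'
#' Builds the standard model ladder on the training lesions:
#' `clinical` (age, PSAD, DRE, zone, lesion volume, PI-RADS dummies),
#' `clinical_adc` (clinical plus MEM_ADC) and `clinical_multib`
#' (clinical plus the stable diffusion predictors from bootstrap-LASSO
#' selection; with an empty stable set it reduces to the clinical
#' model). Each model's operating threshold is frozen on the training
#' predictions by Youden's J.
#'
#' @param train training cohort or lesion table.
#' @param stableSet character vector of stable diffusion predictors
#'   (e.g. `stabilityResult@stableSet`).
#' @param outcome binary outcome column.
#' @return List of class `riskModels`: per model `coef`, `covariates`
#'   and `threshold`, plus the training predictions.
#' @export
fitRiskModels <- function(train, stableSet = character(),
                          outcome = "cspca") {
  df <- .tbl(train)
  mods <- list(
    clinical = .CLINICAL_COVARIATES,
    clinical_adc = c(.CLINICAL_COVARIATES, "MEM_ADC"),
    clinical_multib = c(.CLINICAL_COVARIATES, stableSet))
  out <- lapply(names(mods), function(nm) {
    m <- .fitLogistic(df, mods[[nm]], outcome)
    m$name <- nm
    m$scores_train <- .predictLogistic(m, df)
    m$threshold <- .youdenThreshold(m$scores_train, df[[outcome]])
    m
  })
  names(out) <- names(mods)
  structure(list(models = out, stableSet = stableSet, outcome = outcome),
            class = "riskModels")
}

#' Predict lesion risk from a fitted risk model
#'
#' @param models a `riskModels` object from [fitRiskModels()].
#' @param cohort cohort or lesion table.
#' @param model model name (`"clinical"`, `"clinical_adc"`,
#'   `"clinical_multib"`).
#' @return Numeric vector of predicted csPCa probabilities.
#' @export
predictRisk <- function(models, cohort, model = "clinical_multib") {
  stopifnot(inherits(models, "riskModels"))
  .predictLogistic(models$models[[model]], .tbl(cohort))
}

#' Decision curve analysis
#'
#' Net benefit `NB(t) = TP/n - (FP/n) * t / (1 - t)` of each risk model
#' over a grid of threshold probabilities, with the treat-all and
#' treat-none reference policies.
#'
#' @param scoreList named list of predicted probability vectors.
#' @param labels binary outcome labels.
#' @param thresholds threshold probability grid in (0, 1); 1 is
#'   excluded by construction.
#' @return A [DecisionCurve-class].
#' @export
decisionCurve <- function(scoreList, labels,
                          thresholds = seq(0.05, 0.95, by = 0.01)) {
  stopifnot(is.list(scoreList), !is.null(names(scoreList)))
  labels <- as.numeric(labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  n <- length(labels)
  prev <- mean(labels)
  nb <- function(pred, t)
    sum(pred & labels == 1) / n - sum(pred & labels == 0) / n * t / (1 - t)
  rows <- list()
  for (nm in names(scoreList)) {
    s <- scoreList[[nm]]
    stopifnot(length(s) == n)
    rows[[nm]] <- data.frame(
      threshold = thresholds, model = nm,
      net_benefit = vapply(thresholds, function(t) nb(s >= t, t), 1))
  }
  rows[["treat_all"]] <- data.frame(
    threshold = thresholds, model = "treat_all",
    net_benefit = vapply(thresholds, function(t)
      nb(rep(TRUE, n), t), 1))
  rows[["treat_none"]] <- data.frame(
    threshold = thresholds, model = "treat_none",
    net_benefit = 0)
  new("DecisionCurve", curve = do.call(rbind, c(rows, make.row.names = FALSE)),
      prevalence = prev)
}

#' Zone-aware split-model prediction
#'
#' Routes each lesion to a zone-specific risk model (one fitted on PZ
#' training lesions, one on TZ), emulating conditional use of the best
#' per-zone predictor, and returns the combined score vector.
#'
#' @param cohort cohort or lesion table.
#' @param pzModel,tzModel fitted logistic models (elements of a
#'   `riskModels` fit, or any list with `coef` and `covariates`).
#' @return Numeric vector of predicted probabilities, in table order.
#' @export
zoneAwarePredict <- function(cohort, pzModel, tzModel) {
  df <- .tbl(cohort)
  if (!all(df$zone %in% c("PZ", "TZ")))
    stop("unseen zone label: ",
         paste(setdiff(unique(df$zone), c("PZ", "TZ")), collapse = ", "))
  out <- numeric(nrow(df))
  if (any(df$zone == "PZ"))
    out[df$zone == "PZ"] <- .predictLogistic(pzModel,
                                             df[df$zone == "PZ", , drop = FALSE])
  if (any(df$zone == "TZ"))
    out[df$zone == "TZ"] <- .predictLogistic(tzModel,
                                             df[df$zone == "TZ", , drop = FALSE])
  out
}

#' Fit the exploratory zone-specific split model
#'
#' Fits one logistic model per zone on that zone's training lesions:
#' the PZ model uses the clinical covariates (without the zone term)
#' plus MEM_ADC, the TZ model the clinical covariates plus CTRW_alpha,
#' reflecting the zone-specific best predictors.
#'
#' @param train training cohort or lesion table.
#' @param pzMetric,tzMetric the per-zone diffusion predictors.
#' @param outcome binary outcome column.
#' @return List with `pz`, `tz` model objects and the frozen `threshold`
#'   from the pooled training predictions.
#' @export
fitZoneAwareModel <- function(train, pzMetric = "MEM_ADC",
                              tzMetric = "CTRW_alpha", outcome = "cspca") {
  df <- .tbl(train)
  cov0 <- setdiff(.CLINICAL_COVARIATES, "zone")
  pz <- .fitLogistic(df[df$zone == "PZ", , drop = FALSE],
                     c(cov0, pzMetric), outcome)
  tz <- .fitLogistic(df[df$zone == "TZ", , drop = FALSE],
                     c(cov0, tzMetric), outcome)
  sc <- zoneAwarePredict(df, pz, tz)
  list(pz = pz, tz = tz,
       threshold = .youdenThreshold(sc, df[[outcome]]))
}
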