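## Location-scale (ComBat-style) batch harmonization of lesion-level
## feature tables with empirical-Bayes shrinkage, the cross-vendor
## consistency check, and external validation of frozen risk models.

## moment-matched inverse-gamma hyperparameters for the scale prior
.aprior <- function(d) { m <- mean(d); s2 <- var(d); (2 * s2 + m^2) / s2 }
.bprior <- function(d) { m <- mean(d); s2 <- var(d); (m * s2 + m^3) / s2 }

## EB iteration for one batch: shrink per-feature location gamma and
## scale delta2 toward their parametric priors
.ebSolve <- function(Z, g.hat, d.hat, conv = 1e-8) {
  n <- ncol(Z)
  g.bar <- mean(g.hat); t2 <- var(g.hat)
  a <- .aprior(d.hat); b <- .bprior(d.hat)
  ## degenerate priors (no spread across features): nothing to shrink to
  if (!is.finite(t2) || t2 <= 0 || !is.finite(a) || !is.finite(b))
    return(list(gamma = g.hat, delta2 = d.hat))
  g.new <- g.hat; d.new <- d.hat
  repeat {
    g.prev <- g.new; d.prev <- d.new
    g.new <- (n * t2 * g.hat + d.new * g.bar) / (n * t2 + d.new)
    ss <- rowSums((Z - g.new)^2)
    d.new <- (b + 0.5 * ss) / (n / 2 + a - 1)
    if (max(abs(g.new - g.prev) / pmax(abs(g.prev), 1e-12),
            abs(d.new - d.prev) / pmax(abs(d.prev), 1e-12)) < conv) break
  }
  list(gamma = g.new, delta2 = d.new)
}

## core harmonization on a features x samples matrix
.combatMatrix <- function(Y, batch, mod = NULL, eb = TRUE) {
  batch <- factor(batch)
  if (nlevels(batch) < 2L) return(Y)
  if (any(table(batch) < 2L)) stop("each batch needs >= 2 observations")
  Xb <- model.matrix(~ 0 + batch)
  X <- cbind(Xb, mod)
  if (qr(X)$rank < ncol(X)) {
    ## name the offending biological covariates
    bad <- colnames(mod)[apply(mod, 2, function(c2)
      qr(cbind(Xb, c2))$rank < ncol(Xb) + 1L)]
    stop("design is singular; collinear with batch: ",
         paste(if (length(bad)) bad else "(unknown)", collapse = ", "))
  }
  nb <- ncol(Xb)
  nbatch <- colSums(Xb)
  Bhat <- t(solve(crossprod(X), crossprod(X, t(Y))))   # G x p
  grand <- Bhat[, seq_len(nb), drop = FALSE] %*% (nbatch / sum(nbatch))
  fitted <- Bhat %*% t(X)
  varpool <- rowMeans((Y - fitted)^2)
  varpool <- pmax(varpool, 1e-12)
  covar <- if (is.null(mod)) 0 else
    Bhat[, -seq_len(nb), drop = FALSE] %*% t(mod)
  Z <- (Y - as.numeric(grand) - covar) / sqrt(varpool)

  Yadj <- Z
  for (b in levels(batch)) {
    sel <- batch == b
    Zb <- Z[, sel, drop = FALSE]
    nb1 <- sum(sel)
    g.hat <- rowMeans(Zb)
    d.hat <- pmax(apply(Zb, 1, var), 1e-12)
    est <- if (eb) .ebSolve(Zb, g.hat, d.hat)
    else {
      ## moment matching removes the batch moments exactly; the
      ## population-variance convention makes the operation idempotent
      list(gamma = g.hat, delta2 = d.hat * (nb1 - 1) / nb1)
    }
    Yadj[, sel] <- (Zb - est$gamma) / sqrt(est$delta2)
  }
  Yadj * sqrt(varpool) + as.numeric(grand) + covar
}

#' ComBat-style harmonization of cross-vendor feature tables
#'
#' Removes additive and multiplicative batch (vendor) effects from the
#' diffusion metrics while preserving the variation associated with the
#' protected biological covariates, following the classical empirical-
#' Bayes location-scale model: each metric is standardized against a
#' batch-and-covariate regression, per-batch location and scale
#' estimates are (optionally) shrunk toward parametric priors shared
#' across metrics, and the standardization is inverted. No reference
#' batch is designated: both vendors are adjusted toward the pooled
#' mean. With `eb = FALSE` the per-batch moments are removed exactly
#' (moment matching), which is idempotent.
#'
#' @param cohort a [DiffusionCohort-class] or lesion table.
#' @param batch batch column name (default `"vendor"`).
#' @param covariates biological covariates to preserve (default the
#'   csPCa label).
#' @param eb use parametric empirical-Bayes shrinkage (default `TRUE`).
#' @param assay metric assay harmonized when `cohort` is a
#'   [DiffusionCohort-class].
#' @param metrics metric columns to harmonize (default: all present).
#' @return The input with harmonized metric values.
#' @export
combatHarmonize <- function(cohort, batch = "vendor",
                            covariates = "cspca", eb = TRUE,
                            assay = "measured", metrics = NULL) {
  df <- .tbl(cohort, assay)
  if (is.null(metrics))
    metrics <- intersect(dwiMetricNames(), colnames(df))
  bt <- factor(df[[batch]])
  if (nlevels(bt) < 2L) return(cohort)      # nothing to remove
  mod <- if (length(covariates))
    model.matrix(~ ., data = df[, covariates, drop = FALSE])[, -1, drop = FALSE]
  else NULL
  Y <- t(as.matrix(df[, metrics, drop = FALSE]))
  Yadj <- .combatMatrix(Y, bt, mod, eb = eb)
  .audit("combat", batches = paste(levels(bt), collapse = "|"),
         eb = eb, metrics = length(metrics))
  if (is(cohort, "DiffusionCohort")) {
    m <- SummarizedExperiment::assay(cohort, assay)
    m[metrics, ] <- Yadj
    SummarizedExperiment::assay(cohort, assay) <- m
    return(cohort)
  }
  cohort[, metrics] <- t(Yadj)
  cohort
}

#' Cross-vendor consistency check within pathology groups
#'
#' Mann-Whitney U test per metric comparing the two vendors'
#' distributions within each pathology group (applied after
#' harmonization); a metric is consistent when no group shows a
#' significant vendor difference.
#'
#' @param primary,validation lesion tables (or cohorts) of the two
#'   vendors.
#' @param group pathology grouping column (default `"cspca"`).
#' @param metrics metrics to check (default all 18 present).
#' @param alpha significance level defining "consistent" (default 0.05).
#' @return List with `table` (metric x group p-values) and `nPass`
#'   (number of metrics with p > alpha in every group).
#' @export
crossVendorConsistencyCheck <- function(primary, validation,
                                        group = "cspca", metrics = NULL,
                                        alpha = 0.05) {
  p1 <- .tbl(primary); p2 <- .tbl(validation)
  if (is.null(metrics))
    metrics <- intersect(dwiMetricNames(), intersect(colnames(p1),
                                                     colnames(p2)))
  rows <- list()
  for (gv in sort(unique(c(p1[[group]], p2[[group]])))) {
    a <- p1[p1[[group]] == gv, , drop = FALSE]
    b <- p2[p2[[group]] == gv, , drop = FALSE]
    if (nrow(a) < 3L || nrow(b) < 3L) {
      .audit("consistency", group = gv, skipped = "too few lesions")
      next
    }
    for (m in metrics) {
      wt <- suppressWarnings(wilcox.test(a[[m]], b[[m]], exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = m, group = gv, p = wt$p.value)
    }
  }
  tab <- do.call(rbind, rows)
  pass <- vapply(metrics, function(m)
    all(tab$p[tab$metric == m] > alpha), logical(1))
  list(table = tab, nPass = sum(pass), pass = pass)
}

#' External validation of frozen risk models
#'
#' Applies training-derived risk models to an external cohort without
#' any refitting: coefficients and operating thresholds stay frozen,
#' and performance plus decision curves are computed on the external
#' lesions only.
#'
#' @param models a `riskModels` object from [fitRiskModels()].
#' @param external external cohort or lesion table (harmonize first).
#' @param ciMethod,nBootCI,seed forwarded to [rocMetrics()].
#' @return List with `eval` (named [ModelEval-class] per model),
#'   `decisionCurve` (a [DecisionCurve-class]) and `scores`.
#' @export
externalValidate <- function(models, external, ciMethod = "bootstrap",
                             nBootCI = 2000L, seed = 1L) {
  stopifnot(inherits(models, "riskModels"))
  df <- .tbl(external)
  y <- df[[models$outcome]]
  scores <- lapply(models$models, .predictLogistic, df = df)
  evals <- lapply(names(scores), function(nm)
    rocMetrics(scores[[nm]], y, threshold = models$models[[nm]]$threshold,
               ciMethod = ciMethod, nBootCI = nBootCI, seed = seed))
  names(evals) <- names(scores)
  list(eval = evals, decisionCurve = decisionCurve(scores, y),
       scores = scores)
}
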