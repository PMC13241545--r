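## Cohort splitting, group comparisons with FDR control, rank
## correlation with grade group, and the zone / PI-RADS subgroup
## analyses.

## accept either a DiffusionCohort or a flat lesion table
.tbl <- function(x, assay = "measured") {
  if (is(x, "DiffusionCohort")) cohortTable(x, assay)
  else as.data.frame(x, check.names = FALSE)
}

#' Patient-level train/test split
#'
#' Randomly allocates patients (not lesions) to the training set, with
#' `floor(trainFraction * nPatients)` training patients; all lesions of
#' a patient inherit the patient's label, so no patient straddles the
#' split.
#'
#' @param cohort a [DiffusionCohort-class] or lesion table with a
#'   `patient_id` column.
#' @param trainFraction fraction of patients assigned to training
#'   (default 0.7).
#' @param seed integer seed.
#' @return The input with a `split` column/colData set to `"train"` or
#'   `"test"`.
#' @export
#' @examples
#' coh <- generateCohort(cohortConfig(nPatients = 10, seed = 3))
#' table(lesionData(splitCohort(coh, seed = 1))$split)
splitCohort <- function(cohort, trainFraction = 0.7, seed = 1L) {
  df <- .tbl(cohort)
  pts <- unique(as.character(df$patient_id))
  if (length(pts) < 2L) stop("need at least 2 patients to split")
  nTrain <- floor(trainFraction * length(pts))
  trainP <- .withSeed(seed, sample(pts, nTrain))
  lab <- ifelse(as.character(df$patient_id) %in% trainP, "train", "test")
  if (is(cohort, "DiffusionCohort")) {
    SummarizedExperiment::colData(cohort)$split <- lab
    validObject(cohort)
    return(cohort)
  }
  cohort$split <- lab
  cohort
}

#' Group comparisons with FDR adjustment
#'
#' Two-sided Mann-Whitney U tests for continuous variables (chi-square
#' for categorical ones) between the two levels of `grouping`, with
#' Benjamini-Hochberg adjustment across the compared variables.
#'
#' @param cohort cohort or lesion table.
#' @param variables character vector of columns to compare (default: the
#'   18 diffusion metrics present in the table).
#' @param grouping binary grouping column (default `"cspca"`).
#' @param subset optional logical vector restricting the lesions
#'   compared (a subgroup filter).
#' @return data.frame with `variable`, `test`, `statistic`, `p`,
#'   `p_adj` (BH within this comparison family) and per-group medians.
#' @export
compareGroups <- function(cohort, variables = NULL, grouping = "cspca",
                          subset = NULL) {
  df <- .tbl(cohort)
  if (!is.null(subset)) df <- df[subset, , drop = FALSE]
  if (is.null(variables))
    variables <- intersect(dwiMetricNames(), colnames(df))
  g <- df[[grouping]]
  lev <- sort(unique(g))
  if (length(lev) != 2L) stop("grouping must have exactly two levels")
  if (min(table(g)) < 1L) stop("empty group")
  rows <- lapply(variables, function(v) {
    x <- df[[v]]
    if (is.numeric(x)) {
      if (min(table(g[is.finite(x)])) < 3L)
        stop("Mann-Whitney needs >= 3 observations per group for ", v)
      wt <- suppressWarnings(wilcox.test(x[g == lev[2]], x[g == lev[1]],
                                         exact = FALSE))
      data.frame(variable = v, test = "mann-whitney",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 median_g0 = median(x[g == lev[1]], na.rm = TRUE),
                 median_g1 = median(x[g == lev[2]], na.rm = TRUE))
    } else {
      ct <- suppressWarnings(chisq.test(table(x, g)))
      if (any(ct$expected < 1))
        warning("low expected counts in chi-square for ", v)
      data.frame(variable = v, test = "chi-square",
                 statistic = unname(ct$statistic), p = ct$p.value,
                 median_g0 = NA_real_, median_g1 = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Spearman correlation between metrics and grade group within a zone
#'
#' Rank correlation of each diffusion metric with the ordinal Gleason
#' grade group (0-5) among lesions of one zone, BH-adjusted across
#' metrics.
#'
#' @param cohort cohort or lesion table.
#' @param zone `"PZ"` or `"TZ"`.
#' @param variables metrics to correlate (default: all 18 present).
#' @return data.frame with `variable`, `rho`, `p`, `p_adj`; a constant
#'   metric yields `NA` with a flag column `degenerate`.
#' @export
spearmanByZone <- function(cohort, zone = c("PZ", "TZ"), variables = NULL) {
  zone <- match.arg(zone)
  df <- .tbl(cohort)
  df <- df[df$zone == zone, , drop = FALSE]
  if (nrow(df) < 5L) stop("need >= 5 lesions in zone ", zone)
  if (is.null(variables))
    variables <- intersect(dwiMetricNames(), colnames(df))
  rows <- lapply(variables, function(v) {
    x <- df[[v]]
    if (length(unique(x)) < 2L)
      return(data.frame(variable = v, rho = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    ct <- suppressWarnings(cor.test(x, df$gg, method = "spearman",
                                    exact = FALSE))
    data.frame(variable = v, rho = unname(ct$estimate), p = ct$p.value,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Zone and PI-RADS subgroup analyses
#'
#' Re-runs the per-metric group comparison and single-metric ROC within
#' the standard subgroups: PZ, TZ, PI-RADS 3, PI-RADS 4-5, and the
#' equivocal TZ PI-RADS 3 stratum with both outcomes (any PCa, i.e.
#' grade group >= 1, and csPCa). Strata with fewer than `minN` lesions
#' in either outcome class are flagged; single-class strata are skipped
#' with a log entry.
#'
#' @param cohort cohort or lesion table.
#' @param variables metrics analysed (default: all 18 present).
#' @param minN minimum per-class lesion count before a stratum is
#'   flagged as small (default 10).
#' @return Named list per stratum, each with `n`, `flagged_small`,
#'   `comparison` (from [compareGroups()]) and `auc` (named per-metric
#'   discriminative AUC).
#' @export
subgroupAnalysis <- function(cohort, variables = NULL, minN = 10L) {
  df <- .tbl(cohort)
  if (is.null(variables))
    variables <- intersect(dwiMetricNames(), colnames(df))
  strata <- list(
    PZ          = list(sel = df$zone == "PZ", outcome = "cspca"),
    TZ          = list(sel = df$zone == "TZ", outcome = "cspca"),
    PIRADS3     = list(sel = df$pirads == 3, outcome = "cspca"),
    PIRADS45    = list(sel = df$pirads >= 4, outcome = "cspca"),
    TZ_PIRADS3_PCa   = list(sel = df$zone == "TZ" & df$pirads == 3,
                            outcome = "pca"),
    TZ_PIRADS3_csPCa = list(sel = df$zone == "TZ" & df$pirads == 3,
                            outcome = "cspca"))
  df$pca <- as.integer(df$gg >= 1L)
  out <- list()
  for (nm in names(strata)) {
    st <- strata[[nm]]
    sub <- df[st$sel, , drop = FALSE]
    y <- sub[[st$outcome]]
    if (nrow(sub) == 0L || length(unique(y)) < 2L ||
        min(table(y)) < 3L) {
      .audit("subgroup", stratum = nm,
             skipped = "single-class, empty or below test arity")
      next
    }
    aucs <- vapply(variables, function(v) {
      r <- suppressMessages(pROC::roc(y, sub[[v]], quiet = TRUE,
                                      direction = "auto"))
      as.numeric(pROC::auc(r))
    }, numeric(1))
    out[[nm]] <- list(
      n = table(factor(y, levels = c(0, 1))),
      flagged_small = min(table(y)) < minN,
      comparison = compareGroups(sub, variables, grouping = st$outcome),
      auc = aucs)
    if (out[[nm]]$flagged_small)
      .audit("subgroup", stratum = nm, flag = "small stratum",
             n = paste(table(y), collapse = "/"))
  }
  out
}
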