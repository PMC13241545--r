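## End-to-end pipeline commands and file-format plumbing. Each command
## is a plain function over the package's analysis API; the thin
## command-line wrapper in inst/scripts/multibdwi.R maps subcommands
## onto them. All outputs are deterministic given config + seed (no
## timestamps), and every JSON report embeds the root seed and a config
## hash so double runs can be compared byte for byte.

.configHash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 0
  for (c in utf8ToInt(txt)) h <- (h * 31 + c) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Write a cohort to plain-text files
#'
#' Writes `lesions.csv` (clinical annotation) plus one
#' `metrics_<assay>.csv` per assay (lesions x 18 metrics), UTF-8,
#' comma-separated, "." decimal.
#'
#' @param cohort a [DiffusionCohort-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeCohortCSV <- function(cohort, dir) {
  stopifnot(is(cohort, "DiffusionCohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "lesions.csv")
  write.csv(as.data.frame(lesionData(cohort)), paths[1], row.names = FALSE)
  for (a in SummarizedExperiment::assayNames(cohort)) {
    p <- file.path(dir, paste0("metrics_", a, ".csv"))
    m <- t(SummarizedExperiment::assay(cohort, a))
    out <- data.frame(lesion_id = rownames(m), m, check.names = FALSE)
    write.csv(out, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a cohort from plain-text files
#'
#' @param dir directory written by [writeCohortCSV()].
#' @return A [DiffusionCohort-class].
#' @export
readCohortCSV <- function(dir) {
  les <- read.csv(file.path(dir, "lesions.csv"), check.names = FALSE)
  fl <- list.files(dir, pattern = "^metrics_.*\\.csv$", full.names = TRUE)
  if (!length(fl)) stop("no metric files found in ", dir)
  assays <- list()
  for (p in fl) {
    a <- sub("^metrics_(.*)\\.csv$", "\\1", basename(p))
    m <- read.csv(p, check.names = FALSE)
    stopifnot(identical(m$lesion_id, as.character(les$lesion_id)) ||
                identical(as.character(m$lesion_id),
                          as.character(les$lesion_id)))
    mm <- t(as.matrix(m[, dwiMetricNames(), drop = FALSE]))
    assays[[a]] <- mm
  }
  do.call(DiffusionCohort, c(list(lesionData = les), assays))
}

#' Generate and write a synthetic cohort
#'
#' Runs the synthetic-data generator end to end and writes the cohort
#' tables plus a manifest with the config hash and seed.
#'
#' @param config a [cohortConfig()].
#' @param outDir output directory.
#' @return The generated [DiffusionCohort-class], invisibly.
#' @export
cmdSimulate <- function(config = cohortConfig(), outDir) {
  coh <- generateCohort(config)
  writeCohortCSV(coh, outDir)
  .writeJSON(list(seed = config$seed,
                  config_hash = .configHash(config[
                    setdiff(names(config), c("calibration", "clinical"))]),
                  n_patients = length(unique(lesionData(coh)$patient_id)),
                  n_lesions = ncol(coh)),
             file.path(outDir, "manifest.json"))
  invisible(coh)
}

#' Fit all models to decays from file
#'
#' Accepts either a decay table (CSV whose first column is the b-value
#' and each further column one voxel/ROI signal) or a 4D NIfTI volume
#' with a 3D mask and an FSL-style single-row b-value sidecar. Writes a
#' per-voxel 18-metric table, the ROI-aggregated metric vector, and -
#' for NIfTI input - one 3D parameter map per metric.
#'
#' @param decays path to a decay CSV (mutually exclusive with `dwi`).
#' @param dwi,mask,bvals paths to the 4D DWI NIfTI, 3D mask NIfTI and
#'   b-value sidecar.
#' @param outDir output directory.
#' @param config a [fitConfig()].
#' @return Invisibly, the ROI-aggregated metric vector.
#' @export
cmdFit <- function(decays = NULL, dwi = NULL, mask = NULL, bvals = NULL,
                   outDir, config = fitConfig()) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(decays)) {
    tab <- read.csv(decays, check.names = FALSE)
    b <- tab[[1]]
    sig <- as.matrix(tab[, -1, drop = FALSE])
    ids <- colnames(sig)
    dims <- NULL
  } else {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("NIfTI input requires the RNifti package")
    vol <- RNifti::readNifti(dwi)
    msk <- RNifti::readNifti(mask)
    b <- scan(bvals, quiet = TRUE)
    if (dim(vol)[4] != length(b))
      stop("b-value count (", length(b), ") does not match volume count (",
           dim(vol)[4], ")")
    sel <- which(msk != 0)
    if (!length(sel)) stop("mask is empty")
    dims <- dim(msk)
    sig <- t(matrix(vol, prod(dims), dim(vol)[4])[sel, , drop = FALSE])
    ids <- paste0("v", sel)
  }
  ord <- order(b)
  scheme <- bValueScheme(b[ord])
  res <- matrix(NA_real_, length(ids), 18L,
                dimnames = list(ids, dwiMetricNames()))
  convRate <- setNames(numeric(7), dwiModelFamilies())
  for (i in seq_along(ids)) {
    s <- sig[ord, i]
    fa <- fitAllModels(signalDecay(scheme, s), config)
    res[i, ] <- fa$metrics
    convRate <- convRate + fa$converged
  }
  .audit("cmdFit", voxels = length(ids),
         convergence = paste(names(convRate),
                             round(convRate / length(ids), 2),
                             sep = ":", collapse = " "))
  write.csv(data.frame(id = ids, res, check.names = FALSE),
            file.path(outDir, "voxel_metrics.csv"), row.names = FALSE)
  agg <- roiAggregate(res)
  write.csv(data.frame(metric = names(agg$metrics), value = agg$metrics,
                       n_voxels = agg$nVoxels),
            file.path(outDir, "roi_metrics.csv"), row.names = FALSE)
  if (!is.null(dims)) {
    for (m in dwiMetricNames()) {
      map <- array(NA_real_, dims)
      map[as.integer(sub("^v", "", ids))] <- res[, m]
      RNifti::writeNifti(map, file.path(outDir, paste0(
        "map_", gsub("[^A-Za-z0-9_]", "_", m), ".nii.gz")))
    }
  }
  invisible(agg)
}

.evalToList <- function(ev) {
  list(auc = ev@auc, auc_ci = as.numeric(ev@aucCI), accuracy = ev@accuracy,
       sensitivity = ev@sensitivity, specificity = ev@specificity,
       ppv = ev@ppv, npv = ev@npv, threshold = ev@threshold,
       n = ev@n, prevalence = ev@prevalence)
}

#' Run the full statistical analysis chain on a cohort
#'
#' Pipeline order: reliability gating, reader averaging, patient-level
#' split, group comparisons with FDR (overall and per zone), Spearman
#' versus grade group per zone, bootstrap-LASSO stability selection on
#' the training split, GEE adjusted for clinical covariates, the three
#' nested risk models with ROC/DeLong evaluation on train and test,
#' decision curves, subgroup analyses and the exploratory zone-aware
#' model. Results are written as JSON and CSV.
#'
#' @param cohort a [DiffusionCohort-class] or a directory written by
#'   [cmdSimulate()]/[writeCohortCSV()].
#' @param outDir output directory.
#' @param seed root seed for the split, bootstrap and CI streams.
#' @param nBoot bootstrap resamples for stability selection.
#' @param skipGating bypass the ICC gate (all 18 metrics enter
#'   selection).
#' @param iccThreshold reliability gate (default 0.80).
#' @param trainFraction patient-level training fraction.
#' @param ciMethod AUC CI method (`"delong"` default here: deterministic
#'   and fast; `"bootstrap"` available).
#' @return Invisibly, the report list.
#' @export
cmdAnalyze <- function(cohort, outDir, seed = 1L, nBoot = 500L,
                       skipGating = FALSE, iccThreshold = 0.80,
                       trainFraction = 0.7, ciMethod = "delong") {
  if (is.character(cohort)) cohort <- readCohortCSV(cohort)
  stopifnot(is(cohort, "DiffusionCohort"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  ## 1. reliability gate, then reader averaging
  hasReaders <- all(c("reader1", "reader2") %in%
                      SummarizedExperiment::assayNames(cohort))
  icc <- if (hasReaders) iccTable(cohort) else
    setNames(rep(NA_real_, 18), dwiMetricNames())
  gated <- if (skipGating || !hasReaders) dwiMetricNames()
           else filterByICC(icc, iccThreshold)
  if (hasReaders) cohort <- averageReaders(cohort)

  ## 2. patient-level split
  if (!"split" %in% colnames(lesionData(cohort)))
    cohort <- splitCohort(cohort, trainFraction,
                          seed = .deriveSeed(seed, "split"))
  df <- cohortTable(cohort)
  train <- df[df$split == "train", , drop = FALSE]
  test <- df[df$split == "test", , drop = FALSE]

  ## 3. comparisons and correlations
  cmp <- list(overall = compareGroups(df, gated),
              PZ = compareGroups(df, gated, subset = df$zone == "PZ"),
              TZ = compareGroups(df, gated, subset = df$zone == "TZ"))
  rho <- list(PZ = spearmanByZone(df, "PZ", gated),
              TZ = spearmanByZone(df, "TZ", gated))

  ## 4. stability selection and GEE
  stab <- bootstrapLassoSelect(train, gated, nBoot = nBoot,
                               seed = .deriveSeed(seed, "lasso"))
  geeCov <- c("age", "psad", "dre", "pirads", "zone", "volume",
              stab@stableSet)
  gee <- if (length(stab@stableSet))
    geeFit(df, geeCov, standardize = stab@stableSet) else NULL

  ## 5. risk models, ROC, DeLong, DCA
  models <- fitRiskModels(train, stab@stableSet)
  evalSplit <- function(sub) {
    sc <- lapply(models$models, .predictLogistic, df = sub)
    ev <- lapply(names(sc), function(nm)
      rocMetrics(sc[[nm]], sub$cspca,
                 threshold = models$models[[nm]]$threshold,
                 ciMethod = ciMethod, seed = .deriveSeed(seed, nm)))
    names(ev) <- names(sc)
    list(scores = sc, eval = ev)
  }
  evTrain <- evalSplit(train)
  evTest <- evalSplit(test)
  dl <- list(
    multib_vs_clinical = delongTest(evTest$scores$clinical_multib,
                                    evTest$scores$clinical, test$cspca),
    multib_vs_adc = delongTest(evTest$scores$clinical_multib,
                               evTest$scores$clinical_adc, test$cspca))
  dca <- decisionCurve(evTest$scores, test$cspca)

  ## 6. subgroups and the zone-aware exploratory model
  sg <- subgroupAnalysis(df, gated)
  za <- fitZoneAwareModel(train)
  zaTest <- rocMetrics(zoneAwarePredict(test, za$pz, za$tz), test$cspca,
                       threshold = za$threshold, ciMethod = ciMethod,
                       seed = .deriveSeed(seed, "zoneaware"))

  report <- list(
    seed = seed,
    n = list(patients = length(unique(df$patient_id)), lesions = nrow(df),
             train_patients = length(unique(train$patient_id)),
             test_patients = length(unique(test$patient_id)),
             train_lesions = nrow(train), test_lesions = nrow(test)),
    icc = as.list(icc), gated_metrics = gated,
    selection_frequencies = as.list(stab@frequencies),
    stable_set = stab@stableSet,
    gee = if (!is.null(gee)) lapply(split(gee@coefTable,
                                          rownames(gee@coefTable)),
                                    as.list) else NULL,
    eval_train = lapply(evTrain$eval, .evalToList),
    eval_test = lapply(evTest$eval, .evalToList),
    delong_test = dl,
    zone_aware_test = .evalToList(zaTest),
    subgroup_auc = lapply(sg, `[[`, "auc"))

  .writeJSON(report, file.path(outDir, "analysis.json"))
  .writeJSON(c(lapply(models$models, function(m)
    list(coef = as.list(m$coef), covariates = m$covariates,
         threshold = m$threshold)),
    list(stable_set = stab@stableSet, outcome = models$outcome,
         zone_aware = list(
           pz = list(coef = as.list(za$pz$coef),
                     covariates = za$pz$covariates),
           tz = list(coef = as.list(za$tz$coef),
                     covariates = za$tz$covariates),
           threshold = za$threshold))),
    file.path(outDir, "models.json"))
  write.csv(data.frame(metric = names(stab@frequencies),
                       frequency = stab@frequencies),
            file.path(outDir, "selection_frequencies.csv"),
            row.names = FALSE)
  for (nm in names(cmp))
    write.csv(cmp[[nm]], file.path(outDir, paste0("comparison_", nm, ".csv")),
              row.names = FALSE)
  write.csv(dca@curve, file.path(outDir, "decision_curve_test.csv"),
            row.names = FALSE)
  invisible(report)
}

.modelsFromJSON <- function(path) {
  mj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- c("clinical", "clinical_adc", "clinical_multib")
  models <- lapply(nm, function(n) {
    m <- mj[[n]]
    list(name = n, coef = unlist(m$coef), covariates = m$covariates,
         threshold = m$threshold)
  })
  names(models) <- nm
  structure(list(models = models, stableSet = mj$stable_set,
                 outcome = mj$outcome), class = "riskModels")
}

#' Cross-vendor validation of frozen models
#'
#' Harmonizes the pooled primary + external table with
#' [combatHarmonize()], runs the per-metric cross-vendor consistency
#' check within pathology groups, and applies the frozen
#' training-derived models to the harmonized external lesions.
#'
#' @param modelsPath path to the `models.json` written by
#'   [cmdAnalyze()] (or a `riskModels` object).
#' @param primary primary cohort (object or directory).
#' @param external external cohort (object or directory), with a
#'   distinct `vendor` label.
#' @param outDir output directory.
#' @param seed seed for the evaluation streams.
#' @param ciMethod AUC CI method.
#' @return Invisibly, the validation report list.
#' @export
cmdValidate <- function(modelsPath, primary, external, outDir, seed = 1L,
                        ciMethod = "delong") {
  models <- if (inherits(modelsPath, "riskModels")) modelsPath
            else .modelsFromJSON(modelsPath)
  if (is.character(primary)) primary <- readCohortCSV(primary)
  if (is.character(external)) external <- readCohortCSV(external)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  p1 <- .tbl(primary); p2 <- .tbl(external)
  if (!"vendor" %in% colnames(p2)) stop("external table lacks a vendor column")
  common <- intersect(colnames(p1), colnames(p2))
  pooled <- rbind(p1[, common, drop = FALSE], p2[, common, drop = FALSE])
  pooled <- combatHarmonize(pooled)
  h1 <- pooled[seq_len(nrow(p1)), , drop = FALSE]
  h2 <- pooled[-seq_len(nrow(p1)), , drop = FALSE]
  cons <- crossVendorConsistencyCheck(h1, h2)
  val <- externalValidate(models, h2, ciMethod = ciMethod, seed = seed)
  report <- list(
    seed = seed,
    consistency_pass = cons$nPass,
    consistency = as.list(cons$pass),
    eval_external = lapply(val$eval, .evalToList))
  .writeJSON(report, file.path(outDir, "validation.json"))
  write.csv(cons$table, file.path(outDir, "consistency.csv"),
            row.names = FALSE)
  write.csv(val$decisionCurve@curve,
            file.path(outDir, "decision_curve_external.csv"),
            row.names = FALSE)
  invisible(report)
}
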