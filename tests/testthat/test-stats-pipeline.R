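test_that("cohort splitting is patient-level with floor rounding", {
  coh <- splitCohort(smallCohort(nPatients = 162, seed = 1), seed = 5)
  cd <- as.data.frame(lesionData(coh))
  pat <- unique(cd[, c("patient_id", "split")])
  expect_identical(sum(pat$split == "train"), 113L)
  expect_identical(sum(pat$split == "test"), 49L)
  ## no patient straddles the split (also enforced by class validity)
  expect_true(all(table(pat$patient_id) == 1))
  small <- splitCohort(smallCohort(nPatients = 10, seed = 2), seed = 5)
  p2 <- unique(as.data.frame(lesionData(small))[, c("patient_id", "split")])
  expect_identical(sum(p2$split == "train"), 7L)
  expect_identical(sum(p2$split == "test"), 3L)
})

test_that("group comparisons behave at the extremes and apply BH", {
  df <- data.frame(cspca = rep(0:1, each = 20),
                   a = rep(1:2, each = 20),  # fully separated
                   b = rnorm(40))
  set.seed(1)
  df$b <- rnorm(40)
  res <- compareGroups(df, c("a", "b"))
  expect_lt(res$p[res$variable == "a"], 0.001)
  ## identical groups: p in the non-significant region
  same <- data.frame(cspca = rep(0:1, each = 10), m = rep(1:10, 2))
  expect_gt(compareGroups(same, "m")$p, 0.9)
  ## BH column equals the hand-applied definition
  expect_equal(res$p_adj, p.adjust(res$p, "BH"), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand-applied definition", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  ## oracle: sorted p * m / rank, cumulative minimum from the largest
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(adj, rep(0.04, 4), tolerance = 1e-12)
  expect_equal(p.adjust(p, "BH"), adj, tolerance = 1e-12)
  ## monotonicity and dominance over raw p on random vectors
  set.seed(3)
  for (i in 1:10) {
    pr <- runif(18)
    ad <- p.adjust(pr, "BH")
    expect_true(all(ad >= pr - 1e-15))
    expect_true(all(diff(ad[order(pr)]) >= -1e-15))
  }
})

test_that("Spearman-by-zone matches a direct rank computation", {
  df <- data.frame(zone = "PZ",
                   gg = c(0, 1, 2, 3, 4, 5, 2, 1),
                   m = c(1.2, 1.1, 0.8, 0.9, 0.5, 0.4, 0.85, 1.05))
  res <- spearmanByZone(df, "PZ", "m")
  oracle <- cor(rank(df$m), rank(df$gg))
  expect_equal(res$rho, oracle, tolerance = 1e-12)
  ## perfect monotone relations
  df$up <- df$gg; df$down <- -df$gg
  expect_equal(spearmanByZone(df, "PZ", "up")$rho, 1, tolerance = 1e-12)
  expect_equal(spearmanByZone(df, "PZ", "down")$rho, -1, tolerance = 1e-12)
  ## constant metric flagged degenerate
  df$flat <- 1
  expect_true(spearmanByZone(df, "PZ", "flat")$degenerate)
})

test_that("AUC equals exhaustive pair counting", {
  ## hand-worked 6-point fixture with a tie
  s <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2)
  y <- c(1, 1, 0, 1, 0, 0)
  ev <- rocMetrics(s, y, ciMethod = "delong")
  expect_equal(ev@auc, pairCountAUC(s, y), tolerance = 1e-12)
  ## random fixtures up to 50 lesions
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), 2)             # induce ties
    expect_equal(rocMetrics(s, y, ciMethod = "delong")@auc,
                 pairCountAUC(s, y), tolerance = 1e-12)
  }
})

test_that("rocMetrics confusion identities hold at the operating point", {
  s <- c(0.95, 0.9, 0.8, 0.7, 0.35, 0.3, 0.2, 0.1)
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  ev <- rocMetrics(s, y, ciMethod = "delong")
  expect_identical(ev@auc, 1)
  expect_identical(ev@sensitivity, 1); expect_identical(ev@specificity, 1)
  expect_identical(ev@accuracy, 1)
  ## null scores: AUC near 0.5
  set.seed(2)
  yy <- rbinom(2000, 1, 0.5); ss <- rnorm(2000)
  ev2 <- rocMetrics(ss, yy, ciMethod = "delong")
  expect_gt(ev2@auc, 0.45); expect_lt(ev2@auc, 0.55)
  ## frozen external threshold is honoured and identities hold exactly
  ev3 <- rocMetrics(s, y, threshold = 0.5, ciMethod = "delong")
  tp <- sum(s >= 0.5 & y == 1); tn <- sum(s < 0.5 & y == 0)
  expect_equal(ev3@accuracy, (tp + tn) / 8, tolerance = 1e-12)
  expect_error(rocMetrics(s, rep(1, 8)), "both outcome classes")
})

test_that("the DeLong test is calibrated against itself and extremes", {
  set.seed(8)
  y <- rbinom(500, 1, 0.5)
  a <- y + rnorm(500, 0, 1e-6)          # near-perfect
  b <- rnorm(500)                       # uninformative
  self <- delongTest(a, a, y)
  expect_identical(self$auc_diff, 0)
  expect_identical(self$p, 1)
  expect_lt(delongTest(a, b, y)$p, 0.001)
  expect_error(delongTest(a, b[1:10], y), "paired")
})

test_that("DeLong variance agrees with a bootstrap estimate", {
  set.seed(21)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  x <- y * 0.8 + rnorm(n)
  a <- plogis(x + 0.3 * rnorm(n))
  b <- plogis(0.5 * x + 0.8 * rnorm(n))
  dl <- delongTest(a, b, y)
  zz <- qnorm(1 - dl$p / 2)
  var_delong <- (dl$auc_diff / zz)^2
  boots <- replicate(2000, {
    i <- sample(n, n, replace = TRUE)
    if (length(unique(y[i])) < 2) NA
    else pairCountAUC(a[i], y[i]) - pairCountAUC(b[i], y[i])
  })
  var_boot <- var(boots, na.rm = TRUE)
  expect_lt(abs(var_delong - var_boot) / var_boot, 0.35)
})

test_that("GEE with singleton clusters equals ordinary logistic regression", {
  set.seed(5)
  n <- 300
  df <- data.frame(patient_id = sprintf("P%03d", 1:n),
                   x = rnorm(n), w = rnorm(n))
  df$cspca <- rbinom(n, 1, plogis(-0.3 + 0.8 * df$x))
  fit <- geeFit(df, c("x", "w"))
  ref <- glm(cspca ~ x + w, binomial, df)
  expect_equal(fit@coefTable$coefficient, unname(coef(ref)),
               tolerance = 1e-6)
  expect_identical(fit@nClusters, as.integer(n))
  expect_true(fit@converged)
})

test_that("GEE recovers a known clustered effect", {
  set.seed(77)
  npat <- 1000
  sizes <- sample(1:3, npat, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  id <- rep(seq_len(npat), sizes)
  u <- rep(rnorm(npat, 0, 0.5), sizes)
  x <- rnorm(length(id))
  y <- rbinom(length(id), 1, plogis(0.2 - 1.0 * x + u))
  df <- data.frame(patient_id = id, x = x, cspca = y)
  fit <- geeFit(df, "x")
  est <- fit@coefTable["x", "coefficient"]
  expect_lt(abs(est - (-1.0)), 0.15)
  ## a strongly clustered design drives the working correlation up
  u2 <- rep(rnorm(npat, 0, 2), sizes)
  y2 <- rbinom(length(id), 1, plogis(0.2 + u2))
  fit2 <- geeFit(data.frame(patient_id = id, x = x, cspca = y2), "x")
  expect_gt(fit2@alpha, 0.1)
  ## odds ratio identity
  expect_equal(fit@coefTable$or, exp(fit@coefTable$coefficient),
               tolerance = 1e-12)
})

test_that("GEE null covariates are not spuriously significant", {
  set.seed(31)
  ps <- replicate(20, {
    id <- rep(1:100, sample(1:2, 100, replace = TRUE))
    df <- data.frame(patient_id = id, x = rnorm(length(id)),
                     cspca = rbinom(length(id), 1, 0.4))
    geeFit(df, "x")@coefTable["x", "p"]
  })
  expect_lte(mean(ps < 0.05), 0.2)
})

test_that("bootstrap-LASSO separates planted signal from noise", {
  set.seed(123)
  n <- 200
  y <- rbinom(n, 1, 0.5)
  X <- matrix(rnorm(n * 17), n, 17)
  sig <- y + rnorm(n, 0, 0.7)          # noisy copy of the outcome
  df <- data.frame(patient_id = sprintf("P%03d", 1:n), cspca = y,
                   sig = sig, X)
  metrics <- c("sig", paste0("X", 1:17))
  res <- bootstrapLassoSelect(df, metrics, nBoot = 100, seed = 4)
  expect_gt(res@frequencies[["sig"]], 0.9)
  ## noise features never cross the strict > 0.5 stability rule
  expect_true(all(res@frequencies[paste0("X", 1:17)] <= 0.5))
  expect_identical(res@stableSet, "sig")
  ## determinism
  res2 <- bootstrapLassoSelect(df, metrics, nBoot = 100, seed = 4)
  expect_identical(res@frequencies, res2@frequencies)
  expect_identical(res@lambdas, res2@lambdas)
})

test_that("bootstrap-LASSO returns an empty stable set on pure noise", {
  set.seed(9)
  n <- 150
  df <- data.frame(patient_id = sprintf("P%03d", 1:n),
                   cspca = rbinom(n, 1, 0.5),
                   matrix(rnorm(n * 10), n, 10))
  res <- bootstrapLassoSelect(df, paste0("X", 1:10), nBoot = 60, seed = 2)
  expect_length(res@stableSet, 0)
})

test_that("risk models nest and degrade gracefully", {
  coh <- averageReaders(smallCohort(nPatients = 120, seed = 13))
  df <- cohortTable(splitCohort(coh, seed = 3))
  train <- df[df$split == "train", ]
  mods <- fitRiskModels(train, stableSet = c("MEM_ADC", "CTRW_alpha"))
  dev <- vapply(mods$models, function(m) {
    p <- pmin(pmax(m$scores_train, 1e-12), 1 - 1e-12)
    -2 * sum(train$cspca * log(p) + (1 - train$cspca) * log(1 - p))
  }, numeric(1))
  expect_lte(dev[["clinical_multib"]], dev[["clinical_adc"]] + 1e-8)
  expect_lte(dev[["clinical_adc"]], dev[["clinical"]] + 1e-8)
  ## empty stable set: model 3 falls back to the clinical covariate set
  mods0 <- fitRiskModels(train, stableSet = character())
  expect_identical(mods0$models$clinical_multib$covariates,
                   mods0$models$clinical$covariates)
  ## predictions are probabilities
  p <- predictRisk(mods, df)
  expect_true(all(p > 0 & p < 1))
})

test_that("decision curves satisfy their closed-form identities", {
  set.seed(6)
  y <- rbinom(400, 1, 0.35)
  prev <- mean(y)
  perfect <- as.numeric(y)
  perfect[perfect == 1] <- 0.999; perfect[perfect == 0] <- 0.001
  dc <- decisionCurve(list(perfect = perfect, none = rep(0.001, 400)),
                      y, thresholds = seq(0.05, 0.9, by = 0.05))
  cv <- dc@curve
  ## treat-none is identically zero
  expect_true(all(cv$net_benefit[cv$model == "treat_none"] == 0))
  ## a perfect model attains the prevalence at every threshold
  expect_equal(cv$net_benefit[cv$model == "perfect"],
               rep(prev, 18), tolerance = 1e-12)
  ## treat-all matches prevalence - (1 - prevalence) t/(1-t)
  t <- cv$threshold[cv$model == "treat_all"]
  expect_equal(cv$net_benefit[cv$model == "treat_all"],
               prev - (1 - prev) * t / (1 - t), tolerance = 1e-12)
  ## no curve exceeds the prevalence
  expect_true(all(cv$net_benefit <= prev + 1e-12))
  expect_error(decisionCurve(list(a = perfect), y, thresholds = c(0.5, 1)),
               "inside")
})

test_that("subgroup analysis localises a planted zone-specific effect", {
  set.seed(14)
  n <- 1000
  zone <- rep(c("PZ", "TZ"), each = n / 2)
  cspca <- rbinom(n, 1, 0.45)
  df <- data.frame(patient_id = sprintf("P%04d", 1:n), zone = zone,
                   cspca = cspca, gg = ifelse(cspca == 1, 2, 0),
                   pirads = sample(3:5, n, replace = TRUE))
  ## CTRW_alpha carries signal only in TZ
  df$CTRW_alpha <- 0.9 - 0.06 * cspca * (zone == "TZ") + rnorm(n, 0, 0.04)
  sg <- suppressMessages(subgroupAnalysis(df, "CTRW_alpha"))
  expect_gt(sg$TZ$auc[["CTRW_alpha"]], sg$PZ$auc[["CTRW_alpha"]])
  expect_gt(sg$TZ$auc[["CTRW_alpha"]], 0.7)
  ## a single-zone table reproduces the global comparison in its stratum
  pz <- df[df$zone == "PZ", ]
  sg2 <- suppressMessages(subgroupAnalysis(pz, "CTRW_alpha"))
  expect_equal(sg2$PZ$comparison$p,
               compareGroups(pz, "CTRW_alpha")$p, tolerance = 1e-12)
  ## empty stratum is skipped, not an error
  expect_false("TZ" %in% names(sg2))
})

test_that("zone-aware prediction routes lesions to their zone model", {
  coh <- averageReaders(smallCohort(nPatients = 100, seed = 17))
  df <- cohortTable(splitCohort(coh, seed = 3))
  train <- df[df$split == "train", ]
  za <- fitZoneAwareModel(train)
  sc <- zoneAwarePredict(df, za$pz, za$tz)
  expect_length(sc, nrow(df))
  expect_true(all(sc > 0 & sc < 1))
  ## identical models reduce to pooled prediction
  scSame <- zoneAwarePredict(df, za$pz, za$pz)
  expect_equal(scSame, multibDWI:::.predictLogistic(za$pz, df),
               tolerance = 1e-12)
  ## single-zone table uses only that zone's model
  pzOnly <- df[df$zone == "PZ", ]
  expect_equal(zoneAwarePredict(pzOnly, za$pz, za$tz),
               multibDWI:::.predictLogistic(za$pz, pzOnly),
               tolerance = 1e-12)
  bad <- df; bad$zone[1] <- "CZ"
  expect_error(zoneAwarePredict(bad, za$pz, za$tz), "unseen zone")
})
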