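## Binomial-logit generalized estimating equations with exchangeable
## working correlation and robust (sandwich) standard errors, for
## population-averaged inference on clustered lesions (multiple lesions
## per patient).

## expand covariate names into a design matrix; "pirads" becomes dummy
## variables with category 3 as the reference, "zone" an indicator for TZ
.designMatrix <- function(df, covariates) {
  cols <- list("(Intercept)" = rep(1, nrow(df)))
  for (v in covariates) {
    if (v == "pirads") {
      cols[["PIRADS_4"]] <- as.numeric(df$pirads == 4)
      cols[["PIRADS_5"]] <- as.numeric(df$pirads == 5)
    } else if (v == "zone") {
      cols[["zone_TZ"]] <- as.numeric(df$zone == "TZ")
    } else {
      x <- df[[v]]
      if (is.null(x)) stop("missing covariate column: ", v)
      cols[[v]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Logistic GEE with exchangeable working correlation
#'
#' Fits a marginal (population-averaged) logistic regression by
#' generalized estimating equations, treating lesions of one patient as
#' an exchangeable cluster, and reports robust sandwich standard errors.
#' The exchangeable correlation and the dispersion are re-estimated from
#' Pearson residuals at each iteration (moment estimators). With all
#' clusters of size one the estimates coincide with ordinary logistic
#' regression.
#'
#' @param cohort cohort or lesion table.
#' @param covariates character vector of covariate names; `"pirads"`
#'   expands to PI-RADS 4 and 5 dummies (category 3 reference),
#'   `"zone"` to a TZ indicator.
#' @param outcome binary outcome column (default `"cspca"`).
#' @param cluster cluster id column (default `"patient_id"`).
#' @param standardize covariates to z-score before fitting (typically
#'   the diffusion metrics, so their odds ratios are per standard
#'   deviation; clinical covariates conventionally stay in native
#'   units).
#' @param maxIter,tol iteration control.
#' @return A [GEEResult-class] with per-covariate coefficient, odds
#'   ratio, robust SE, z and p-value.
#' @export
geeFit <- function(cohort, covariates, outcome = "cspca",
                   cluster = "patient_id", standardize = character(),
                   maxIter = 50L, tol = 1e-10) {
  df <- .tbl(cohort)
  for (v in intersect(standardize, colnames(df)))
    df[[v]] <- as.numeric(scale(df[[v]]))
  y <- as.numeric(df[[outcome]])
  stopifnot(all(y %in% 0:1))
  X <- .designMatrix(df, covariates)
  id <- as.character(df[[cluster]])
  p <- ncol(X)
  n <- length(y)
  cl <- split(seq_len(n), id)

  beta <- tryCatch(
    suppressWarnings(coef(glm.fit(X, y, family = binomial()))),
    error = function(e) rep(0, p))
  if (anyNA(beta)) stop("singular design in GEE fit")
  alpha <- 0; phi <- 1
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    ## variance floor keeps the working covariance invertible when a
    ## fitted probability saturates numerically
    a <- pmax(mu * (1 - mu), 1e-8)
    e <- (y - mu) / sqrt(pmax(a, 1e-12))
    phi <- sum(e^2) / (n - p)
    num <- 0; den <- 0
    for (ix in cl) {
      ni <- length(ix)
      if (ni > 1L) {
        s <- sum(e[ix])^2 - sum(e[ix]^2)
        num <- num + s / 2
        den <- den + ni * (ni - 1) / 2
      }
    }
    alpha <- if (den > p) .clip(num / (phi * (den - p)), 0, 0.95) else 0
    U <- matrix(0, p, 1); B <- matrix(0, p, p); M <- matrix(0, p, p)
    for (ix in cl) {
      ni <- length(ix)
      Ai <- a[ix]
      Di <- X[ix, , drop = FALSE] * Ai
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Vi <- phi * (sqrt(Ai) %o% sqrt(Ai)) * Ri
      Wi <- solve(Vi)
      ri <- y[ix] - mu[ix]
      DtW <- crossprod(Di, Wi)
      U <- U + DtW %*% ri
      B <- B + DtW %*% Di
      M <- M + (DtW %*% ri) %*% t(DtW %*% ri)
    }
    delta <- solve(B, U)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("GEE did not converge in ", maxIter, " iterations")
  ## separation check on the standardized scale (covariates keep their
  ## native units, so raw coefficients can be legitimately large)
  if (any(abs(beta * apply(X, 2, sd)) > 15))
    warning("very large standardized GEE coefficients; possible separation")
  Binv <- solve(B)
  V <- Binv %*% M %*% Binv
  se <- sqrt(diag(V))
  z <- beta / se
  tab <- data.frame(coefficient = beta, or = exp(beta), robust_se = se,
                    z = z, p = 2 * pnorm(-abs(z)),
                    row.names = colnames(X))
  new("GEEResult", coefTable = tab, corstr = "exchangeable",
      alpha = alpha, nIter = it, converged = converged,
      nClusters = length(cl))
}
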