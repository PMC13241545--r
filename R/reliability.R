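## Inter-reader reliability: two-way intraclass correlation, the ICC
## gate applied before feature selection, and reader averaging.

#' Two-way intraclass correlation coefficient for two readers
#'
#' Computes the single-rater ICC from the classical two-way mean-squares
#' decomposition across lesions (rows) and readers (columns). The default
#' `"agreement"` variant is the two-way random-effects absolute-agreement
#' ICC, ICC(2,1), which penalizes systematic offsets between readers;
#' `"consistency"` gives ICC(3,1), invariant to a constant reader offset.
#'
#' @param reader1,reader2 numeric vectors of the two readers' values per
#'   lesion (same length, >= 3 lesions).
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`
#'   (ICC(3,1)).
#' @return ICC value in `[-1, 1]`.
#' @export
#' @examples
#' x <- rnorm(50); iccTwoWay(x, x)        # 1
#' iccTwoWay(x, x + rnorm(50, sd = 2))    # low
iccTwoWay <- function(reader1, reader2,
                      type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(length(reader1) == length(reader2))
  ok <- is.finite(reader1) & is.finite(reader2)
  if (any(!ok)) stop("reader values must be finite and paired")
  n <- length(reader1)
  if (n < 3L) stop("ICC needs at least 3 lesions")
  k <- 2L
  y <- cbind(reader1, reader2)
  grand <- mean(y)
  rowm <- rowMeans(y); colm <- colMeans(y)
  if (all(abs(y - grand) < 1e-300)) stop("zero total variance: ICC undefined")
  msr <- k * sum((rowm - grand)^2) / (n - 1)                # lesions
  msc <- n * sum((colm - grand)^2) / (k - 1)                # readers
  sse <- sum((y - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "consistency")
    return((msr - mse) / (msr + (k - 1) * mse))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Per-metric inter-reader ICC of a cohort
#'
#' @param cohort a [DiffusionCohort-class] with `reader1` and `reader2`
#'   assays.
#' @param type ICC variant, see [iccTwoWay()].
#' @return Named numeric vector of ICC values for the 18 metrics.
#' @export
iccTable <- function(cohort, type = "agreement") {
  stopifnot(is(cohort, "DiffusionCohort"))
  r1 <- SummarizedExperiment::assay(cohort, "reader1")
  r2 <- SummarizedExperiment::assay(cohort, "reader2")
  vapply(rownames(r1), function(m) iccTwoWay(r1[m, ], r2[m, ], type = type),
         numeric(1))
}

#' Reliability gate on metrics
#'
#' Retains metrics whose inter-reader ICC meets the reliability
#' threshold (default 0.80, stricter than the conventional 0.75) and
#' logs every gating decision.
#'
#' @param icc named numeric vector of per-metric ICC values.
#' @param threshold minimum ICC to retain a metric.
#' @return Character vector of retained metric names.
#' @export
filterByICC <- function(icc, threshold = 0.80) {
  stopifnot(!is.null(names(icc)))
  keep <- names(icc)[icc >= threshold]
  drop <- setdiff(names(icc), keep)
  .audit("icc-gate", threshold = threshold, retained = length(keep),
         excluded = if (length(drop)) paste(drop, collapse = "|") else "none")
  keep
}

#' Average the two readers' measurements
#'
#' Arithmetic mean of the reader replicates per lesion-metric; the
#' result is stored as (or returned in place of) the `measured` assay
#' used for all downstream analysis.
#'
#' @param cohort a [DiffusionCohort-class] with `reader1` and `reader2`
#'   assays (or a numeric matrix paired with `reader2`).
#' @param reader2 second reader matrix when `cohort` is a matrix.
#' @return The cohort with its `measured` assay set to the reader mean,
#'   or the averaged matrix.
#' @export
averageReaders <- function(cohort, reader2 = NULL) {
  if (is(cohort, "DiffusionCohort")) {
    an <- SummarizedExperiment::assayNames(cohort)
    if (!all(c("reader1", "reader2") %in% an))
      stop("cohort lacks reader replicate assays")
    m <- (SummarizedExperiment::assay(cohort, "reader1") +
            SummarizedExperiment::assay(cohort, "reader2")) / 2
    SummarizedExperiment::assay(cohort, "measured") <- m
    return(cohort)
  }
  if (is.null(reader2)) stop("missing second reader")
  stopifnot(identical(dim(cohort), dim(reader2)))
  (as.matrix(cohort) + as.matrix(reader2)) / 2
}
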