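## Internal plumbing: seed streams, reproducible RNG scopes, distribution
## parameter inversion from median/IQR summaries, logging.

## deterministic 31-bit stream seed derived from a root seed and a label
.deriveSeed <- function(root, label) {
  h <- as.numeric(root) %% 2147483647
  for (c in utf8ToInt(as.character(label)))
    h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

## evaluate expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.Z75 <- qnorm(0.75)  # 0.6744898

## log-normal (mu, sigma) whose median and quartiles match m (q1-q3);
## sigma from the symmetrised log-IQR
.lnormFromQuartiles <- function(m, q1, q3) {
  stopifnot(m > 0, q1 > 0, q3 >= q1)
  list(mu = log(m), sigma = (log(q3) - log(q1)) / (2 * .Z75))
}

## logit-normal on (0, hi) for bounded metrics
.logitnormFromQuartiles <- function(m, q1, q3, hi = 1) {
  lg <- function(x) qlogis(pmin(pmax(x / hi, 1e-6), 1 - 1e-6))
  list(mu = lg(m), sigma = (lg(q3) - lg(q1)) / (2 * .Z75), hi = hi)
}

.quantileFun <- function(dist) {
  if (!is.null(dist$hi))
    function(p) dist$hi * plogis(dist$mu + dist$sigma * qnorm(p))
  else
    function(p) exp(dist$mu + dist$sigma * qnorm(p))
}

## structured audit log line (stage, then key=value pairs) to stderr,
## suppressible via suppressMessages()
.audit <- function(stage, ...) {
  kv <- list(...)
  msg <- paste0("[", stage, "] ",
                paste(names(kv), vapply(kv, function(x)
                  paste(format(x), collapse = ","), character(1)),
                  sep = "=", collapse = " "))
  message(msg)
  invisible(msg)
}

## clip into [lo, hi]
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
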