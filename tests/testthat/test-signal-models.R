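test_that("every model returns exactly S0 at b = 0", {
  for (ps in refParamSets())
    expect_identical(as.numeric(dwiSignal(ps, 0)), 1)
  ps2 <- modelParamSet("MEM", adc = 2.2, s0 = 137.5)
  expect_identical(as.numeric(memSignal(ps2, 0)), 137.5)
})

test_that("signal equations match their closed forms", {
  expect_equal(memSignal(modelParamSet("MEM", adc = 1), 1000), exp(-1),
               tolerance = 1e-12)
  ## representative group-median parameter values
  expect_equal(memSignal(modelParamSet("MEM", adc = 0.87), 3000),
               exp(-2.61), tolerance = 1e-12)
  expect_equal(semSignal(modelParamSet("SEM", ddc = 1.02, alpha = 0.69), 2000),
               exp(-(2000 * 1.02e-3)^0.69), tolerance = 1e-12)
  expect_equal(
    ivimSignal(modelParamSet("IVIM", d = 0.81, dstar = 13.43, f = 0.16), 800),
    0.16 * exp(-800 * 13.43e-3) + 0.84 * exp(-800 * 0.81e-3),
    tolerance = 1e-12)
  expect_equal(dkiSignal(modelParamSet("DKI", d = 1.18, k = 0.73), 1500),
               exp(-1500 * 1.18e-3 + 1500^2 * (1.18e-3)^2 * 0.73 / 6),
               tolerance = 1e-12)
  expect_equal(
    as.numeric(ivimDkiSignal(
      modelParamSet("IVIM_DKI", d = 0.92, dp = 20.93, f = 0.18, k = 0.59),
      1000)),
    0.18 * exp(-1000 * 20.93e-3) +
      0.82 * exp(-1000 * 0.92e-3 + 1e6 * (0.92e-3)^2 * 0.59 / 6),
    tolerance = 1e-12)
  ## FROC with mu entering as a length in mm
  expect_equal(
    frocSignal(modelParamSet("FROC", d = 1.01, beta = 0.75, mu = 7.40), 2500),
    exp(-1.01e-3 * (7.40e-3)^(2 * (0.75 - 1)) * 2500^0.75),
    tolerance = 1e-12)
  ## CTRW against a high-precision Mittag-Leffler reference
  expect_equal(
    ctrwSignal(modelParamSet("CTRW", d = 1.01, alpha = 0.83, beta = 0.76),
               3000),
    0.14954115759035302, tolerance = 1e-9)
})

test_that("reduction lattice holds to 1e-10 over the 0-3000 b-grid", {
  b <- seq(0, 3000, by = 125)
  mem <- memSignal(modelParamSet("MEM", adc = 1.11), b)
  rel <- function(x, y) max(abs(x - y) / pmax(abs(y), 1e-300))
  expect_lt(rel(semSignal(modelParamSet("SEM", ddc = 1.11, alpha = 1), b),
                mem), 1e-10)
  expect_lt(rel(ivimSignal(modelParamSet("IVIM", d = 1.11, dstar = 20,
                                         f = 0), b), mem), 1e-10)
  expect_lt(rel(as.numeric(dkiSignal(modelParamSet("DKI", d = 1.11, k = 0),
                                     b)), mem), 1e-10)
  expect_lt(rel(as.numeric(ivimDkiSignal(
    modelParamSet("IVIM_DKI", d = 1.11, dp = 20, f = 0, k = 0), b)),
    mem), 1e-10)
  expect_lt(rel(frocSignal(modelParamSet("FROC", d = 1.11, beta = 1,
                                         mu = 7.5), b), mem), 1e-10)
  ## beta = 1 removes the mu dependence entirely
  expect_identical(
    frocSignal(modelParamSet("FROC", d = 1.11, beta = 1, mu = 3), b),
    frocSignal(modelParamSet("FROC", d = 1.11, beta = 1, mu = 18), b))
  expect_lt(rel(ctrwSignal(modelParamSet("CTRW", d = 1.11, alpha = 1,
                                         beta = 1), b), mem), 1e-10)
  ## CTRW at alpha = 1 collapses onto the stretched exponential
  expect_lt(rel(
    ctrwSignal(modelParamSet("CTRW", d = 1.11, alpha = 1, beta = 0.76), b),
    semSignal(modelParamSet("SEM", ddc = 1.11, alpha = 0.76), b)), 1e-10)
})

test_that("signals decay monotonically in b for valid parameters", {
  set.seed(42)
  b <- sort(c(0, runif(20, 1, 3000)))
  for (rep in 1:10) {
    sets <- list(
      modelParamSet("SEM", ddc = runif(1, 0.3, 3), alpha = runif(1, 0.4, 1)),
      modelParamSet("IVIM", d = runif(1, 0.3, 2), dstar = runif(1, 5, 50),
                    f = runif(1, 0, 0.4)),
      modelParamSet("CTRW", d = runif(1, 0.3, 3), alpha = runif(1, 0.4, 1),
                    beta = runif(1, 0.4, 1)),
      modelParamSet("FROC", d = runif(1, 0.3, 3), beta = runif(1, 0.4, 1),
                    mu = runif(1, 2, 15)))
    for (ps in sets)
      expect_true(all(diff(as.numeric(dwiSignal(ps, b))) <= 1e-12))
  }
  ## DKI decays monotonically up to the turning point of its quadratic
  ## exponent, b = 3 / (D K)
  ps <- modelParamSet("DKI", d = 1.2, k = 1.5)
  bb <- b[b <= 3 / (1.2e-3 * 1.5)]
  expect_true(all(diff(as.numeric(dkiSignal(ps, bb))) <= 1e-12))
})

test_that("domain violations raise errors", {
  expect_error(memSignal(modelParamSet("MEM", adc = 1), -10), "b-values")
  expect_error(modelParamSet("SEM", ddc = 1, alpha = 1.2), "alpha")
  expect_error(modelParamSet("IVIM", d = 1, dstar = 10, f = 1.1), "f must")
  expect_error(modelParamSet("IVIM", d = 1, dstar = 0.5, f = 0.1),
               "exceed tissue diffusion")
  expect_error(modelParamSet("DKI", d = 1, k = -0.1), "kurtosis")
  expect_error(modelParamSet("FROC", d = 1, beta = 0, mu = 7), "beta")
  ## zero diffusivity is storable (fit boundary) but not evaluable
  zero <- modelParamSet("MEM", adc = 0)
  expect_error(memSignal(zero, 1000), "positive diffusivity")
})

test_that("DKI flags b-values beyond the validity guard instead of erroring", {
  ps <- modelParamSet("DKI", d = 1.18, k = 0.73)
  s <- dkiSignal(ps, c(1000, 2500, 3000))
  expect_equal(attr(s, "b_beyond_validity"), c(2500, 3000))
  expect_null(attr(dkiSignal(ps, 1500), "b_beyond_validity"))
})

test_that("Mittag-Leffler closed-form anchors hold to 1e-8", {
  expect_identical(mittagLeffler(0.6, 0), 1)
  expect_equal(mittagLeffler(1, -1), exp(-1), tolerance = 1e-12)
  z <- seq(-5, 0, by = 0.5)
  expect_equal(mittagLeffler(1, z), exp(z), tolerance = 1e-12)
  ## E_{1/2}(z) = exp(z^2) erfc(-z); erfc via the normal cdf
  erfc <- function(x) 2 * pnorm(-x * sqrt(2))
  expect_equal(mittagLeffler(0.5, -1), exp(1) * erfc(1), tolerance = 1e-8)
  expect_equal(mittagLeffler(0.5, -3.5), exp(3.5^2) * erfc(3.5),
               tolerance = 1e-8)
})

test_that("Mittag-Leffler matches high-precision reference values", {
  ## 40-digit arbitrary-precision references (power series summed at
  ## high precision; small-alpha entries from the spectral integral,
  ## cross-validated where both converge)
  ref <- data.frame(
    alpha = c(0.1, 0.1, 0.1, 0.1, 0.25, 0.25, 0.4, 0.5, 0.69, 0.69,
              0.75, 0.83, 0.83, 0.9, 0.9, 0.99, 0.99, 0.1, 0.3, 0.6, 0.85),
    z = c(-0.1, -1, -2, -5, -1, -3.5, -5, -2, -1, -5,
          -5, -1, -5, -3.5, -5, -1, -5, -12, -8, -12, -12),
    E = c(0.90476574225743151, 0.4855644643110821, 0.3200153359597274,
          0.15804238235845183, 0.46385276080171329, 0.19326848542426085,
          0.12462707110373716, 0.25539567631050574, 0.40094630461305493,
          0.079423947756276038, 0.067923974332643942, 0.38345815552838566,
          0.051027580770487654, 0.06385427373575243, 0.034431324804098418,
          0.36854831806033962, 0.0097680921391741282, 0.072432284945913166,
          0.089493095818620724, 0.038643078839373573, 0.015323981406109334))
  got <- mapply(mittagLeffler, ref$alpha, ref$z)
  expect_equal(got, ref$E, tolerance = 1e-8)
})

test_that("Mittag-Leffler agrees with a brute-force series oracle where it converges", {
  ## independent double-precision series, usable where cancellation is
  ## provably mild (alpha >= 0.4, |z| <= 5)
  seriesML <- function(alpha, z, kmax = 300) {
    k <- 0:kmax
    sum(z^k / gamma(alpha * k + 1))
  }
  ## the double-precision oracle itself cancels catastrophically for
  ## small alpha at large |z| (largest term ~ |z|^k / Gamma(alpha k + 1)),
  ## so it is only consulted where its own error is provably < 1e-10
  for (alpha in c(0.6, 0.7, 0.85, 0.95, 1)) {
    for (z in seq(if (alpha < 0.7) -4 else -5, -0.5, by = 0.75)) {
      expect_equal(mittagLeffler(alpha, z), seriesML(alpha, z),
                   tolerance = 1e-8,
                   label = sprintf("E_%g(%g)", alpha, z))
    }
  }
})

test_that("Mittag-Leffler domain checks and monotonicity", {
  expect_error(mittagLeffler(0, -1), "alpha")
  expect_error(mittagLeffler(1.3, -1), "alpha")
  expect_error(mittagLeffler(0.5, 1), "z must")
  for (alpha in c(0.3, 0.6, 0.9)) {
    v <- mittagLeffler(alpha, seq(0, -10, by = -0.5))
    expect_true(all(diff(v) < 0))       # completely monotone => decreasing
    expect_true(all(v > 0 & v <= 1))
  }
})
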