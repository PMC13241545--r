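---
title: "Multi-b-value diffusion models and zone-specific csPCa analysis: methods"
author: "multibDWI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-b-value diffusion models and zone-specific csPCa analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibDWI)
```

# Scope

`multibDWI` implements the quantitative core of a zone-aware diffusion-MRI
workup for clinically significant prostate cancer (csPCa, ISUP grade group
>= 2): seven multi-b-value signal models yielding 18 lesion-level metrics,
reliability gating, bootstrap-LASSO stability selection, clustered logistic
inference by GEE, nested risk models with ROC and decision-curve
evaluation, and ComBat-style cross-vendor harmonization. Because clinical
DWI cohorts of this kind are not publicly shareable, the package carries a
first-class synthetic cohort generator whose defaults encode the study
design the analysis assumes; every stage is exercised end to end on
generated data.

# The seven signal models

All models describe the magnitude signal $S(b)$ of a diffusion-weighted
acquisition as a function of the b-value (s/mm^2). Diffusivities are
reported in the conventional unit of $10^{-3}$ mm$^2$/s; the equations
apply the $10^{-3}$ factor internally so that $b \cdot D$ is
dimensionless.

* Mono-exponential (MEM): $S = S_0 e^{-b\,\mathrm{ADC}}$ — the Gaussian
  reference model.
* Stretched exponential (SEM): $S = S_0 e^{-(b\,\mathrm{DDC})^\alpha}$,
  $\alpha \in (0,1]$ indexing intravoxel heterogeneity.
* IVIM: $S = S_0 [f e^{-b D^*} + (1-f) e^{-b D}]$, separating
  perfusion-driven pseudo-diffusion ($D^*$, fraction $f$) from tissue
  diffusion.
* DKI: $S = S_0 e^{-b D + b^2 D^2 K/6}$, with kurtosis $K \ge 0$; the
  quadratic expansion is only trusted up to `bMaxDki` (default
  2000 s/mm^2), beyond which values are flagged, not refused.
* Hybrid IVIM-DKI: perfusion compartment plus kurtosis tissue
  compartment.
* FROC: $S = S_0 \exp(-D\,\mu^{2(\beta-1)} b^\beta)$ with spatial
  fractional order $\beta$ and a spatial constant $\mu$.
* CTRW: $S = S_0\,E_\alpha(-(bD)^\beta)$ with the one-parameter
  Mittag-Leffler function $E_\alpha$; $\alpha$ and $\beta$ are temporal
  and spatial heterogeneity indices.

The models form a reduction lattice — every non-Gaussian model collapses
onto MEM in the appropriate parameter limit ($\alpha = 1$, $f = 0$,
$K = 0$, $\beta = 1$), and CTRW at $\alpha = 1$ collapses onto SEM. The
test suite asserts these reductions to $10^{-10}$ relative error on a
0–3000 s/mm^2 grid; they are the strongest cheap consistency check the
model family admits.

## Mittag-Leffler numerics

$E_\alpha(z) = \sum_k z^k/\Gamma(\alpha k + 1)$ is needed only for
$0 < \alpha \le 1$ and $z \le 0$, where it is completely monotone with
values in $(0,1]$. The power series is exact but cancels catastrophically
in double precision once its largest term dwarfs the result (small
$\alpha$, large $|z|$). `mittagLeffler()` therefore sums the series with a
running cancellation bound and, when that bound exceeds $10^{-10}$,
switches to the spectral representation

$$E_\alpha(-x) = \frac{\sin(\alpha\pi)}{\pi\alpha} \int_0^\infty
\frac{e^{-(ux)^{1/\alpha}}}{u^2 + 2u\cos(\alpha\pi) + 1}\,du,$$

the classical complete-monotonicity integral after the substitution
$u = r^\alpha$, which removes the endpoint singularity. The integrand
degenerates as $\alpha \to 1$ (a quasi-pole at $u = 1$), exactly where the
series is well conditioned, so the two regimes cover each other. Against
40-digit arbitrary-precision references the implementation is accurate to
better than $3\times10^{-11}$ over $\alpha \in [0.1, 1]$,
$z \in [-12, 0]$; the only region above $10^{-8}$ relative error is the
sliver $\alpha > 0.99$, $|z| > 10$, which the CTRW fit touches only
transiently.

# Fitting

`fitModel()` minimizes the residual sum of squares under box constraints
with Levenberg-Marquardt, from one data-driven start plus seeded
Latin-hypercube starts (5 total), with deterministic tie-breaking (lowest
RSS, then lexicographically smallest parameter vector) so that identical
inputs give bitwise-identical results. Default bounds: D-type
$[0.05, 4]\times10^{-3}$ mm$^2$/s, $D^*/D_p \in [3, 100]\times10^{-3}$,
$f \in [0, 0.5]$, $\alpha, \beta \in [0.1, 1]$, $K \in [0, 3]$,
$\mu \in [1, 20]$. Parameters within tolerance of a bound are flagged
`atBound`. Per-family b-value subsets: IVIM uses $b \le 1000$ (with all
low-b points), DKI $b \le 2000$, IVIM-DKI $b \le 2500$ — still well
inside kurtosis-expansion validity, $b \ll 3/(DK)$, for prostate values,
and needed to separate kurtosis curvature from perfusion — and the other
families the full scheme. The default 12-point scheme is
0, 50, 100, 150, 200, 500, 800, 1000, 1500, 2000, 2500, 3000 s/mm^2.

Three estimator choices deserve explanation:

* **MEM** is fitted in closed form by weighted log-linear regression
  (weights $\propto S^2$, the first-order variance correction for
  log-transformed magnitudes); a negative slope clips to ADC = 0 with the
  boundary flag set.
* **IVIM** uses the standard segmented strategy: tissue $D$ from
  $b \ge 200$ mono-exponentially, then $S_0, f, D^*$ with $D$ fixed,
  followed by a joint polish from the segmented solution. The pure
  two-step scheme leaves a small $D$ bias from residual perfusion above
  the split; the polish removes it while keeping the deterministic
  initialization. A fully joint fit is available
  (`ivimStrategy = "joint"`) and agrees with the segmented fit on clean
  decays.
* **IVIM-DKI** uses an alternating staged scheme (default): the kurtosis
  tissue pair $(D, K)$ is estimated on the perfusion-free range
  ($b \ge 200$, after subtracting the current perfusion estimate), then
  $(f, D_p)$ with the tissue pair fixed, for three alternations. The
  joint five-parameter likelihood has a strong $f$/$K$ trade-off whose
  estimator has heavy tails at realistic SNR; the staged scheme is the
  hybrid-model analogue of segmented IVIM and is markedly more stable,
  while agreeing with the joint fit to $<0.1\%$ on noiseless decays.
* **FROC** is fitted on *squared* magnitudes with a free noise-floor
  term, using the exact Rician second moment
  $\mathbb{E}[M^2] = S^2 + 2\sigma^2$. FROC's full-scheme b-range decays
  deepest below the noise floor, where plain magnitude least squares
  biases $D$ low by several percent; the floor term removes that bias.
  The same device degrades the CTRW $\alpha$ estimate (the floor trades
  against the Mittag-Leffler tail), so CTRW keeps magnitude least
  squares.

## The FROC identifiability convention

In the simplified b-value form the decay depends on $(D, \mu, \beta)$
only through $\beta$ and the product $A = D\,\mu^{2(\beta-1)}$: $D$ and
$\mu$ lie on an exact ridge and cannot be separated from a single decay.
The package makes this explicit rather than hiding it in optimizer
noise: $\mu$ is profiled out at a documented reference (default 7.5, the
centre of the range reported for prostate tissue, configurable via
`frocMuRef`), is flagged `atBound` as convention-fixed, and $\beta$ and
the product $A$ are recovered exactly. A free joint fit
(`frocMuRef = NULL`) reproduces vendor-like behaviour, returning some
point on the ridge. The reported FROC_D is therefore conditional on the
$\mu$ reference; with truth $\mu = 7.4$ and reference 7.5 the induced
$D$ offset is $(7.4/7.5)^{2(\beta-1)} - 1 \approx 0.7\%$ at
$\beta = 0.75$. $\mu$ itself is quoted on the literature scale (values
around 7, conventionally micrometres; it enters the exponent as a length
in mm) without asserting a physical unit, since reported conventions
conflict.

# The synthetic cohort generator

`generateCohort()` emulates the design the analysis assumes, not images:

* **Patients and clustering.** Default 162 eligible patients (the
  screening bookkeeping 245 screened minus 25 + 15 + 33 + 10 exclusions
  is available via `screeningSummary()`); 28.3% of patients carry 2–3
  lesions (65/35), giving ~224 lesions in expectation. All lesions of a
  patient share the patient's covariates and a patient-level random
  intercept on the csPCa logit scale (SD 0.5 by default — the clustered
  analysis needs a non-zero intra-patient correlation, whose magnitude is
  a generator assumption).
* **Labels.** Lesions are peripheral-zone with probability 0.442;
  per-zone csPCa prevalence defaults to 0.616 (PZ) and 0.368 (TZ), with
  an odds ratio of 2 per doubling of PSA density. Grade group and
  PI-RADS are drawn from conditional tables given csPCa status, and
  csPCa = 1 exactly when grade group >= 2 — an invariant enforced by the
  `DiffusionCohort` validity method.
* **Metrics.** Each of the 18 metrics is drawn from a zone- and
  group-specific distribution calibrated by median/IQR inversion
  (log-normal for positive metrics, logit-normal for (0,1)-bounded shape
  metrics — matching the skewed median (IQR) convention of quantitative
  DWI tables; see `metricCalibration()`). Because a log-normal is
  right-skewed, the IQR *width* is matched while the individual quartiles
  are symmetric on the transformed scale. Tissue-diffusivity metrics
  share a Gaussian-copula rank correlation of 0.7; other pairs are
  conditionally independent (the true inter-metric correlation structure
  is not identifiable from published summaries, so it is a configurable
  assumption).
* **Planted-predictor mode.** With `effectMetrics = c("MEM_ADC",
  "CTRW_alpha")` only the named metrics differ between pathology groups;
  all others are drawn from the non-csPCa calibration for both groups,
  and the copula coupling between planted and null metrics is zeroed so
  the null metrics are genuinely outcome-independent. This is the
  configuration under which exact stable-set recovery is a well-posed
  expectation for the selection pipeline.
* **Readers and vendors.** Two reader replicates per lesion-metric are
  simulated with additive jitter calibrated per metric through the
  variance-components identity $\mathrm{ICC} = \sigma_b^2/(\sigma_b^2 +
  \sigma_e^2)$ to a target ICC (default 0.9, comfortably above the 0.80
  gate, matching the finding that all metrics pass). Vendor (batch)
  effects are location-scale perturbations of the measurement assays.
* **Decays.** `generateDecay()` adds Rician noise — the magnitude of the
  complex Gaussian-noised forward signal — at a configurable b = 0 SNR
  (default 50).
* All randomness flows from one root seed through labelled sub-streams
  (a 31-bit polynomial hash of seed and stream label), so every artefact
  is reproducible and independent stages draw from independent streams.

What the generator does *not* emulate: image-level artifacts, anatomy,
co-registration error, PI-RADS reader behaviour beyond a conditional
table, or realistic correlation between clinical covariates beyond the
PSAD association. A pipeline passing on generated data therefore
demonstrates algorithmic correctness at the study's design points, not
clinical performance on real lesions.

# The statistical pipeline

The stages mirror the standard order of such an analysis: ICC gating,
reader averaging, patient-level 70/30 split (floor rule: 162 patients
give 113/49; no patient straddles the split, enforced at the class
level), Mann-Whitney/chi-square comparisons with Benjamini-Hochberg
adjustment per comparison family, Spearman correlation with grade group
per zone, bootstrap-LASSO selection, GEE, nested risk models, ROC,
DeLong, decision curves and subgroups.

* **ICC.** `iccTwoWay()` computes the two-way random-effects
  absolute-agreement single-rater ICC(2,1) from the mean-squares
  decomposition (the conservative, standard choice for continuous
  radiology measurements; the consistency variant ICC(3,1) is an
  option). The gate retains metrics with ICC >= 0.80.
* **Stability selection.** Per bootstrap resample, whole *patients* are
  drawn with replacement (consistent with the patient-level split and the
  GEE clustering; lesion-level resampling is a config option), metrics
  are z-scored within the resample, an L1-penalized logistic path is
  fitted and the penalty chosen by five-fold cross-validation at the
  deviance minimum. Cross-validation folds are assigned per resampled
  cluster: if bootstrap copies of one lesion straddle folds, the CV curve
  is optimistically biased at small penalties and the selection grossly
  over-includes — with naive folds roughly 12 of 18 null metrics cross
  the 50% stability threshold, with cluster-aware folds the planted pair
  is recovered exactly. Metrics selected in more than half the resamples
  are stable.
* **GEE.** Binomial-logit generalized estimating equations with an
  exchangeable working correlation and robust sandwich errors,
  implemented in-package; moment estimators for the dispersion and
  working correlation are refreshed each iteration, and with singleton
  clusters the estimates coincide with ordinary logistic regression to
  $10^{-6}$ (asserted). PI-RADS enters as dummies with category 3 the
  reference. Diffusion metrics are z-scored for the GEE so their odds
  ratios are per standard deviation; clinical covariates stay in native
  units.
* **Risk models.** `clinical` (age, PSAD, DRE, zone, lesion volume,
  PI-RADS dummies), `clinical_adc` (plus MEM_ADC), `clinical_multib`
  (plus the stable set; with an empty stable set it reduces to the
  clinical model). Operating thresholds are frozen on training
  predictions by Youden's J (deterministic: smallest maximizer) and
  reused unchanged on test and external data. Perfect-separation fits
  fall back to a lightly ridge-penalized refit with a warning.
* **Evaluation.** AUC is the Mann-Whitney (trapezoidal) estimator —
  asserted equal to exhaustive concordant-pair counting on every small
  fixture — with DeLong or stratified-bootstrap confidence intervals;
  confusion rates come from the frozen threshold. Decision curves use
  $NB(t) = TP/n - (FP/n)\,t/(1-t)$ with treat-all/treat-none references.
  The exploratory zone-aware model routes PZ lesions to a
  clinical + MEM_ADC model and TZ lesions to a clinical + CTRW_alpha
  model, each fitted on its zone's training lesions.

# Harmonization

`combatHarmonize()` implements the classical empirical-Bayes
location-scale batch model for feature tables: metrics are standardized
against a batch-and-covariate regression, per-batch location/scale
estimates are shrunk toward parametric priors shared across metrics, and
the transform is inverted, preserving the protected covariates (csPCa by
default; protecting pathology is the natural choice since the
cross-vendor consistency check conditions on it). No reference batch is
designated. The empirical-Bayes mode reproduces the canonical reference
implementation to its convergence tolerance (asserted against `sva` in
the test suite). The moment-matching mode (`eb = FALSE`) removes batch
moments exactly and — with the population-variance convention chosen here
deliberately — is exactly idempotent; the EB mode is not exactly
idempotent (shrinkage leaves a small residual), which is canonical
behaviour, not an implementation artefact. Cross-vendor consistency is a
per-metric Mann-Whitney test between vendors within each pathology
group, applied after harmonization.

# Numerical and design choices, in brief

* Tolerances: LM `ftol` $10^{-10}$, multi-start tie-break window
  $10^{-12}$; Mittag-Leffler series/integral crossover at a $10^{-10}$
  cancellation bound; ICC undefined (error) at zero total variance;
  predictions clamped to $[10^{-12}, 1-10^{-12}]$ because `plogis`
  saturates in double precision.
* Degenerate inputs: non-convergent fits return `converged = FALSE`
  (never silent `NaN`); families whose arity or b-range requirements the
  scheme cannot meet are reported missing with flags; degenerate
  (single-class) bootstrap resamples are redrawn and counted;
  single-class subgroup strata are skipped with a log line.
* Determinism: one root seed, labelled sub-streams, fixed multi-start
  seed, deterministic tie-breaks, no timestamps in outputs; the
  simulate + analyze double-run is asserted bit-identical.

# Problem sizes used by the shipped checks

The test suite and the acceptance script run the pipeline at the study's
design counts (162 + 76 patients, ~224 + ~84 lesions), 100 bootstrap
resamples for stability selection (the full 500 remains the
`cmdAnalyze()` default), 200 noise replicates per family for the
fitting-bias checks, and 10,000 draws for calibration checks. These sizes
make every check reproducible on a single CPU in a few minutes while
keeping Monte-Carlo error well inside the asserted bands.

# Known limitations

* The FROC spatial constant is identified only by convention (above).
* Median-bias guarantees for the pseudo-diffusion and kurtosis
  parameters at SNR 50 hold for the staged estimator; the joint
  five-parameter IVIM-DKI estimator has visibly heavier tails.
* The generator's marginals are calibrated to published group summaries;
  joint structure beyond the diffusivity copula and the PSAD association
  is assumed, not estimated.
* Real-data mode expects pre-extracted lesion tables or simple 4D
  NIfTI + mask inputs; no motion/eddy correction, registration or
  denoising is provided.
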