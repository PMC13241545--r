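# multibDWI

Quantitative multi-b-value diffusion MRI modelling and zone-specific
statistical analysis for clinically significant prostate cancer (csPCa,
ISUP grade group ≥ 2). The package is aimed at imaging scientists and
biostatisticians who work with advanced diffusion protocols (b-values up
to 3000 s/mm²) and need a tested, reproducible implementation of the full
chain from signal decays to cross-vendor-validated risk models.

## What it implements

**Seven signal models, 18 metrics.** Forward equations and constrained
nonlinear fitting for

| Model | Signal equation | Parameters |
|---|---|---|
| MEM | S₀·exp(−b·ADC) | ADC |
| SEM | S₀·exp(−(b·DDC)^α) | DDC, α |
| IVIM | S₀·[f·e^(−b·D*) + (1−f)·e^(−b·D)] | D, D*, f |
| DKI | S₀·exp(−b·D + b²D²K/6) | D, K |
| IVIM-DKI | perfusion + kurtosis compartments | D, Dp, f, K |
| CTRW | S₀·E_α(−(b·D)^β) | D, α, β |
| FROC | S₀·exp(−D·μ^(2(β−1))·b^β) | D, β, μ |

with E_α the one-parameter Mittag-Leffler function (implemented to
~1e−8 relative accuracy on the negative real axis), yielding the 18
`ModelName_ParameterName` metrics (MEM_ADC, ..., FROC_mu). Fitting is
bounded Levenberg-Marquardt with deterministic multi-start, segmented
IVIM, staged IVIM-DKI and a Rician-noise-floor-aware FROC estimator.

**A calibrated synthetic cohort generator.** Clustered patients/lesions
with zone, PI-RADS, grade-group and csPCa labels, group- and
zone-specific metric distributions (median/IQR-calibrated log-/logit-
normals with a diffusivity copula), two-reader replicates, Rician-noised
decays and two-vendor batch effects — so the whole pipeline is testable
without patient data.

**The statistical chain.** Inter-reader ICC(2,1) gating at 0.80, reader
averaging, patient-level 70/30 split, Mann-Whitney/chi-square comparisons
with Benjamini-Hochberg FDR, Spearman-vs-grade-group per zone,
bootstrap-LASSO stability selection (patient-level resampling,
cluster-aware 5-fold CV, stability threshold 50%), logistic GEE with
exchangeable working correlation and sandwich errors, three nested risk
models (clinical / +ADC / +multi-b DWI), ROC with DeLong comparisons,
decision-curve analysis, zone and PI-RADS subgroup analyses, an
exploratory zone-aware split model, and ComBat-style empirical-Bayes
harmonization with a cross-vendor consistency check and frozen-model
external validation.

## Worked example

Fit a noisy continuous-time random-walk decay, then run the selection
pipeline on a synthetic cohort with planted predictors:

```r
library(multibDWI)

ps <- modelParamSet("CTRW", d = 1.01, alpha = 0.83, beta = 0.76)
decay <- generateDecay(ps, defaultBScheme(), snr = 50, seed = 7)
fitModel(decay, "CTRW")
#> FitResult [CTRW] converged, rss = 0.00241719, iterations = 9
#>      s0       d   alpha    beta
#> 1.04275 1.08800 0.77834 0.65519
```

One noisy 12-point decay recovers the CTRW parameters only roughly
(D 1.09 vs 1.01, here with α and β trading against each other) — which is
exactly why the analysis aggregates over lesions and gates on
reliability. At cohort scale:

```r
cfg <- cohortConfig(nPatients = 162,
                    effectMetrics = c("MEM_ADC", "CTRW_alpha"), seed = 42)
coh <- averageReaders(generateCohort(cfg))
coh <- splitCohort(coh, seed = 42)
train <- subset(cohortTable(coh), split == "train")

bootstrapLassoSelect(train, nBoot = 100, seed = 42)
#> StabilityResult over 100 bootstrap resamples
#>    MEM_ADC CTRW_alpha  FROC_beta    SEM_DDC     CTRW_D    FROC_mu
#>       1.00       1.00       0.47       0.39       0.35       0.27
#> stable set (freq > 0.5 ): MEM_ADC, CTRW_alpha
```

The two metrics that actually carry the pathology signal are selected in
every bootstrap resample; the 16 noise metrics all stay below the 50%
stability threshold. GEE then confirms both as independent predictors
after adjusting for the clinical covariates and the within-patient
clustering (odds ratios per standard deviation):

```r
gee <- geeFit(cohortTable(coh),
              c("age", "psad", "dre", "pirads", "zone", "volume",
                "MEM_ADC", "CTRW_alpha"),
              standardize = c("MEM_ADC", "CTRW_alpha"))
gee@coefTable[c("MEM_ADC", "CTRW_alpha"), ]
#>            coefficient     or robust_se       z      p
#> MEM_ADC        -3.0806 0.0459    0.6158 -5.0024 0.0000
#> CTRW_alpha     -1.8343 0.1597    0.8052 -2.2780 0.0227
```

Lower ADC and lower CTRW α mean denser, more heterogeneous tissue, so
odds ratios below 1 are the expected direction. `cmdSimulate()`,
`cmdAnalyze()` and `cmdValidate()` run the same chain end to end with CSV
and JSON outputs (a thin CLI lives in `inst/scripts/multibdwi.R`).

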