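# Shared fixtures: representative parameter sets (group medians of the
# default calibration) and small seeded cohorts.

refParamSets <- function() {
  list(
    MEM = modelParamSet("MEM", adc = 1.11),
    SEM = modelParamSet("SEM", ddc = 1.02, alpha = 0.69),
    IVIM = modelParamSet("IVIM", d = 1.03, dstar = 14.73, f = 0.19),
    DKI = modelParamSet("DKI", d = 1.18, k = 0.73),
    IVIM_DKI = modelParamSet("IVIM_DKI", d = 0.92, dp = 20.93, f = 0.18,
                             k = 0.59),
    CTRW = modelParamSet("CTRW", d = 1.30, alpha = 0.92, beta = 0.76),
    FROC = modelParamSet("FROC", d = 1.01, beta = 0.75, mu = 7.40))
}

noiselessDecay <- function(params, scheme = defaultBScheme()) {
  signalDecay(scheme, as.numeric(dwiSignal(params, bValues(scheme))))
}

smallCohort <- function(nPatients = 40, seed = 7, ...) {
  suppressMessages(generateCohort(cohortConfig(nPatients = nPatients,
                                               seed = seed, ...)))
}

# exhaustive concordant-pair AUC (midrank tie convention): the
# independent oracle for every ROC computation
pairCountAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}
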