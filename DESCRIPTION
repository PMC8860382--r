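Package: selattn
Title: Selectivity, Noise-Correlation and Circuit-Model Analyses of Learning
    and Attention in Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for two-photon calcium-imaging population
    recordings from mouse primary visual cortex across learning and
    attention-switching conditions. Provides a seeded synthetic-session
    generator with ground truth, dF/F preprocessing (neuropil correction,
    running-minimum baseline, trial alignment), per-cell stimulus-selectivity
    statistics (selectivity index, rank tests, recruited cells, behavioral
    d-prime, bootstrap slope comparisons), population analyses
    (difference-PSTHs with PCA, pairwise noise correlations, running-speed
    stratification and lick-trial controls), a multivariate autoregressive
    functional-interaction model with leave-one-out cross-validation, and a
    stochastic four-population (PYR/PV/SOM/VIP) rate-circuit simulator with
    additive or multiplicative top-down modulation, including the
    modulation-target sweep and ratio scan used to identify circuit
    mechanisms of attention.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
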