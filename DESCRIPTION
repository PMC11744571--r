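Package: brainbreaks
Title: Multilevel Analysis of Acute Exercise Breaks: Retinal Microvasculature,
    Cortical Hemodynamics, and Executive Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing acute exercise-break crossover studies that
    combine dual-task Stroop behavior, retinal vessel calibers, and functional
    near-infrared spectroscopy (fNIRS). Implements revised Knudtson central
    retinal arteriolar/venular equivalents (CRAE/CRVE/AVR), inverse efficiency
    scoring with z-normalization, modified Beer-Lambert law conversion with
    channel quality control and PCA denoising, canonical-HRF GLMs fitted by
    autoregressive iteratively reweighted least squares, vector-autoregressive
    Granger-causality networks summarized by causal density, linear mixed models
    with estimated-marginal-means contrasts and assumption diagnostics, and
    covariate-adjusted mediation with bias-corrected bootstrap inference. A
    synthetic-data module generates study-structured datasets, including a
    packaged effect profile, so the full pipeline can be exercised and validated
    by parameter recovery without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    lme4,
    lmerTest,
    emmeans,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
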