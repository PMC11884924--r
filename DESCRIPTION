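Package: hrvdbs
Title: Heart Rate Variability Analysis for Deep Brain Stimulation Block Paradigms
Version: 0.1.0
Authors@R:
    person("HRV-DBS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: End-to-end heart-rate-variability (HRV) analysis for block-design
    deep-brain-stimulation (DBS) experiments in disorders-of-consciousness
    cohorts. Converts single-lead ECG to cleaned RR-interval series (powerline
    notch, Pan-Tompkins-style R-peak detection, ectopic correction), computes
    the eight standard short-segment HRV indices (mRRI, SDNN, TP, LF, HF, nLF,
    nHF, LF/HF) via 4 Hz cubic-spline resampling, smoothness-priors detrending
    and Burg autoregressive spectral estimation, maps stimulation schedules to
    Pre/On/Post phase segments, runs the associated repeated-measures and
    group statistics, and fits a linear support-vector prognosis classifier
    with exact Shapley feature attribution and cross-validated AUC. Includes
    an integral-pulse-frequency-modulation (IPFM) cohort simulator with
    injectable, stimulation-locked autonomic effects so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
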