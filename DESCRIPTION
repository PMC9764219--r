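Package: coroflow
Title: One-Dimensional Coronary Hemodynamics and Streamlined FFR Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile blood flow through branching coronary artery
    trees with a one-dimensional MacCormack finite-difference solver, an
    integral stenosis pressure-loss element, and personalized inlet waveform
    and two-element Windkessel outlet boundary conditions, to compute
    fractional flow reserve (FFR) in silico. Includes variance-based global
    uncertainty quantification of FFR with respect to clinical inputs (Sobol
    indices estimated from Saltelli designs with bootstrap confidence
    intervals), a reclassification resampling study, diagnostic evaluation
    statistics (confusion metrics, ROC, Bland-Altman), streamlined
    minimal-input model configurations, and synthetic generators for
    Murray-law coronary trees, canonical inflow waveforms, and patient
    cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
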