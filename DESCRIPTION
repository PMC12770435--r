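Package: atrialyte
Title: Electrolyte Sensitivity of Human Atrial Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multiscale simulation and analysis of how clinically relevant
    changes in extracellular potassium, sodium and calcium alter human atrial
    electrophysiology and arrhythmia behaviour. Implements an
    electrolyte-parameterised modified Courtemanche-Ramirez-Nattel (CRN++)
    atrial myocyte model with fibrosis remodelling and per-current electrolyte
    override masks, a monodomain reaction-diffusion solver for 1D strands and
    2D sheets, activation/repolarisation biomarker maps, a synthetic fibrotic
    substrate generator emulating LGE-MRI intensity-ratio cohorts, Latin
    hypercube designs with Gaussian-process emulation and variance-based Sobol
    sensitivity analysis, burst-pacing and spiral-wave arrhythmia induction
    protocols with binary endpoint extraction, and machine-learning endpoint
    attribution via permutation importance and exact Shapley values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lhs,
    randomForest,
    xgboost,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
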