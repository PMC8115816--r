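Package: wormpred
Title: Behavioural Change Detection in Worm Pose Dynamics via Prediction Error
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify changes in Caenorhabditis elegans locomotor
    dynamics as one-step-ahead prediction error. Pose time series expressed
    as eigenworm coefficients are time-delay embedded into a reference
    library attractor; out-of-sample poses are predicted with the locally
    weighted S-Map method and prediction error is reported as RMS body-angle
    error, whole-body and per body region, together with a phase-velocity
    behavioural classifier (forward / backward / tight turn). Includes a
    synthetic pose-series generator with ground truth for validation,
    parameter robustness scans over embedding dimension and S-Map
    nonlinearity, and workflows for within-worm change detection, escape
    response analysis and cross-individual prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
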