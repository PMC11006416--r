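Package: apemu
Title: Neural Network Emulation of Paced Ventricular Action Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for emulating the paced human ventricular cardiomyocyte
    action potential with a neural network surrogate. A reduced ionic
    simulator with nine scalable current magnitudes generates paced action
    potentials; a two-stage encoder/decoder network maps conductance scaling
    factors to the full transmembrane-potential time course; a projected
    gradient fitter solves the inverse problem of estimating conductances and
    pharmacological scaling factors from control and drugged action
    potentials. Includes action-potential biomarkers and early
    afterdepolarization detection, population-of-models calibration,
    pore-block drug modelling, and preprocessing of noisy multi-beat
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    data.table,
    signal,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
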