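Package: protodebor
Title: Mechanistic Prediction of Boronic Acid Protodeboronation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the aqueous protodeboronation rate of boronic acids as a
    function of pH from a small set of mechanistic descriptors. Each boronic
    acid is assigned a structural category that determines which of seven
    mechanistic pathways (k1, k2, k2Ar, k2cat, k3, k4, k5) are active; the
    maximum log-rate of each pathway is calibrated by linear regression
    against a DFT-derived characteristic energy difference; piecewise-linear
    log(k) versus pH curves are assembled from pKa, pKaH and fixed
    mechanistic slopes, and summed in rate space into the observed-rate
    profile. Includes leave-one-out cross-validation by molecule, a
    competing-reaction kinetics simulator for yield analysis, and a
    synthetic-data generator with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    ChemmineR,
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
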