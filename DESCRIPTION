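Package: moanet
Title: Interpretable Drug-Signaling Models for Target Inference and
    Mechanism-of-Action Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Trains interpretable recurrent models of intracellular
    signaling constrained by a prior-knowledge network. A drug module maps
    compound doses onto signaling nodes through known drug-target
    interactions scaled by chemical (Tanimoto) similarity; a recurrent
    network propagates the signal to a steady state and predicts
    transcription-factor activities. Ensembles of trained models are used
    to infer unknown drug-target interactions by integrated-gradient
    attribution with an error-curve cutoff, to quantify off-target effects
    on transcription factors, to extract minimal mechanism-of-action
    subnetworks, and to run in-silico knockouts. Includes quality-control
    filters for replicate transcription-factor activity matrices and
    seeded generators of synthetic networks and datasets with planted
    off-target interactions for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
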