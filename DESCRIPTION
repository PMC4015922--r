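Package: polreg
Title: Regulatory Transcription Factor Prediction from RNA Polymerase II
    Promoter Binding Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-step workflow for predicting regulatory transcription
    factors from paired RNA polymerase II (PolII) ChIP-seq promoter binding
    tracks. Implements MA-plot LOWESS normalization of paired binned count
    tracks, pi-value (fold change times -log10 Fisher p) differential
    promoter-binding calls, position weight matrix scanning of promoter
    sequences with corpus-wide rank thresholds, regulatory-capacity scoring
    of motifs by an ensemble of random-subset least-squares regressions,
    backward stepwise finalization over a grid of TSS sub-intervals, and
    inference of a TF co-binding interaction network scored by a significant
    interaction score (SIS). Ships a ground-truthed synthetic data generator
    so the full pipeline is testable without external ChIP-seq downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
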