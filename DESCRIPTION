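Package: cindy
Title: Inference of Transcription Factor Modulators from Expression Data
    via Conditional Mutual Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-scale inference of candidate post-translational
    modulators of transcription factor activity from gene expression
    profiles.  Estimates full conditional mutual information between a
    transcription factor and its targets given a candidate modulator,
    using a rank-space adaptive partitioning estimator, and assesses
    significance against an MI-stratified permutation null with
    extended-exponential tail extrapolation.  Includes the classic
    tail-based delta-I heuristic as a baseline, precision/recall
    benchmarking against protein-protein interaction gold standards, and
    a synthetic-data generator with planted three-way modulation events.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
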