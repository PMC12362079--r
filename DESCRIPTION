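Package: eegmvpa
Title: Time-Resolved EEG Decoding, Cluster Permutation Inference, and
    Population Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern analysis of epoched infant EEG. Provides a
    synthetic multi-subject epoch generator with known ground-truth class
    effects; trial-level preparation (baseline correction, class balancing,
    session concatenation, binary relabeling); per-timepoint linear decoding
    with stratified cross-validation and Haufe activation-pattern feature
    importance; group-level sign-flip permutation inference (cluster mass and
    cluster depth tests); per-subject full-trial decoding with a compact
    convolutional network or a fast linear decoder plus shuffled-label
    permutation nulls; and Bayesian estimation of the population prevalence of
    above-chance decoding (MAP and highest-density interval). A simple
    on-disk epochs container and a pipeline orchestrator tie the stages
    together reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
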