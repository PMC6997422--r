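Package: ksref
Title: Indirect Reference Intervals from Mixed Laboratory Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates clinical reference intervals from routine
    laboratory data that mixes physiological and pathological results.
    The estimator fits a Gaussian distribution to a Box-Cox-transformed,
    truncated part of the observed distribution by minimizing a penalized
    Kolmogorov-Smirnov distance over the transformation parameter, the
    Gaussian parameters and the truncation interval. Includes percentile
    bootstrap confidence intervals for the estimated reference limits, a
    contamination simulation harness for validating the estimator, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
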