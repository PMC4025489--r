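Package: admixbias
Title: Sample Selection Bias in Population Structure and Ancestry Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how biased sampling of admixed versus unmixed
    individuals degrades individual ancestry inference, and to correct for it.
    Includes a Balding-Nichols founder generator calibrated by F_ST, a
    forward-time admixture simulator with local-ancestry segment tracking, an
    admixture-likelihood EM engine (with weighted and semi-supervised
    variants) and standardized eigenanalysis, a group-level selection model
    with resampling and weighted-likelihood corrections, piecewise-constant
    demographies with harmonic-mean effective size, and experiment runners
    that sweep sampling designs and report squared-correlation accuracy.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
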