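Package: gbrnmf
Title: Group- and Basis-Restricted Non-Negative Matrix Factorisation for
    Single-Cell Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Chemometric toolkit for single-cell Raman microspectroscopy of
    irradiated cancer cells. Implements the full analysis chain: spectral
    preprocessing (cosmic-ray removal, asymmetric-least-squares baseline
    subtraction, area normalisation), basis-restricted non-negative matrix
    factorisation in which most factors are fixed to a library of reference
    biochemical spectra while one factor is estimated freely from the data,
    principal-component validation of score trends, group summaries and
    correlation statistics on the factor scores, and random-forest
    classification of radio-sensitivity with permutation (mean decrease
    accuracy) variable importance. A synthetic-spectra generator with known
    ground truth emulates the dose/day/cell-line study design so that every
    stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    randomForest,
    stats,
    tools,
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
RoxygenNote: 7.3.3
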