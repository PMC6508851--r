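Package: rrgrowth
Title: Random-Regression Genomic Prediction for Longitudinal Growth Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction of longitudinal phenotypes (such as image-derived
    projected shoot area) with random-regression models on normalized Legendre
    polynomials. Provides REML estimation (average-information with
    expectation-maximization fallback) of Kronecker-structured covariance
    functions with a VanRaden genomic relationship matrix, per-time-point gBLUP,
    time-varying heritability and genetic-correlation surfaces, forecasting
    cross-validation scenarios, and a calibrated synthetic-data generator that
    emulates a partially replicated multi-experiment rice shoot-growth study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
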