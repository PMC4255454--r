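Package: fastla
Title: Fast Genome-Wide Liquid Association Screening and Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Two-stage search for liquid association -- three-way
    coexpression in which the correlation of a gene pair depends on the
    expression level of a third, controller gene.  Stage one screens all
    ordered gene triplets with a fast tertile correlation-difference
    statistic (rho_diff = rho_high - rho_low) computed by per-bin matrix
    cross-products; stage two estimates modified liquid association for
    the retained triplets under a trivariate conditional normal model
    (full and simple variants) with Wald inference, falling back to a
    robust binned direct estimator with bootstrap standard errors when
    the model fits poorly.  Includes normal-quantile preprocessing,
    Benjamini-Hochberg adjustment against the genome-scale test count,
    synthetic-data generators, and validation analyses of the screen
    against exhaustive estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
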