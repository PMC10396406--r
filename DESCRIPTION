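Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization with a Synthetic
    GWAS Testbed
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pseudo two-sample bidirectional Mendelian
    randomization from GWAS summary statistics: genome-wide significance
    filtering and greedy LD clumping, allele harmonization between an
    exposure and an outcome study, the inverse-variance-weighted estimator
    under a multiplicative random-effects model, MR-Egger regression with
    its intercept test and the I-squared-GX dilution statistic, the
    weighted median estimator with parametric bootstrap standard errors,
    Cochran Q / I-squared heterogeneity, Cook's-distance outlier
    diagnostics, winner's-curse / sample-overlap bias approximation,
    split-sample MR with fixed-effect meta-analysis, and a fully seeded
    generative model of two-cohort GWAS data with known ground truth so
    every stage can be verified by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
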