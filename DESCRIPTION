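Package: gwasdiff
Title: Case-Case Interaction GWAS, LD Score Regression and Polygenic Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing two case-control genome-wide association
    studies at the level of individual variants. Implements the Altman-Bland
    difference-of-log-odds-ratio (interaction) test between two harmonized
    summary-statistic sets, genomic-inflation diagnostics (lambda and
    lambda-1000), a compact LD score regression estimator for SNV-based
    heritability and cross-trait genetic correlation with block-jackknife
    standard errors, clumping-and-thresholding polygenic risk scores with
    observed- and liability-scale variance explained, fixed-effect
    meta-analysis, and a liability-threshold genotype simulator with shared
    and group-specific polygenic components for end-to-end validation of the
    whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
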