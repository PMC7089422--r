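Package: lipidmr
Title: Two-Sample and Multivariable Mendelian Randomisation for Correlated
    Lipid Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation (MR) of highly
    correlated lipoprotein lipid exposures on a binary disease outcome,
    centred on separating the direct effect of apolipoprotein B from the
    effects of LDL cholesterol, triglycerides, HDL cholesterol and
    apolipoprotein A-I. Implements inverse-variance-weighted, MR-Egger,
    weighted-median and weighted-mode estimators, multivariable MR with
    conditional F-statistics, greedy LD clumping, summary-statistic
    harmonisation with proxy substitution, and a synthetic-data generator
    that reproduces the statistical structure of a lipid GWAS plus an
    independent case-control outcome sample, so the whole pipeline is
    testable without individual-level cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
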