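Package: qpcrpanel
Title: Longitudinal qPCR Gene-Panel Analysis with Permutation-Tested
    Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of a targeted qPCR gene panel in a
    longitudinal two-group (case-conversion) cohort: Livak 2^(-ddCt)
    normalization against a reference gene, z-score standardization on a
    reference group, covariate-adjusted logistic regression per gene with
    permutation p-values and Benjamini-Hochberg false-discovery-rate
    correction, co-expression principal-component analysis with
    component-level group tests, clinical-score and DNA-methylation
    correlation analyses, and a synthetic-cohort generator that emulates
    the cohort structure the analysis assumes so every stage is testable
    without access to the original data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
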