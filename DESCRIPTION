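Package: ihtrules
Title: Mining High-Mortality Diagnosis Combinations in Interhospital
    Transfer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies combinations of coded diagnoses associated with
    high in-hospital mortality among interhospital-transfer patients.
    Converts raw ICD-style diagnosis records into six-subcategory binary
    indicators, mines 1-4 item antecedents with a fixed mortality
    consequent using an Apriori search with an absolute left-hand support
    floor, prunes redundant rules with a minimum-improvement criterion,
    and estimates unadjusted and covariate-adjusted odds ratios (the
    latter via an iteratively reweighted least squares logistic fit).
    Includes a seeded synthetic-cohort generator with planted high-risk
    diagnosis combinations so the whole pipeline is testable without
    access to protected health records, and consistency checks that
    reconstruct contingency tables from published summary percentages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
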