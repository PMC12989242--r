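Package: psdocr
Title: Performance-Status Documentation Analysis for Cancer EHR Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure how often cancer patients' performance status
    (ECOG/WHO/Zubrod or Karnofsky) is documented in free-text electronic
    health records. Provides a rule-based extractor for French and English
    performance-status mentions with negation and family-context scoping,
    incident-cancer cohort construction from ICD-10 claims events with a
    24-month washout and an auditable exclusion cascade, documentation
    prevalence cross-tabulations, hospital volume-documentation rank
    correlation, and logistic regression of documentation propensity with
    restricted-cubic-spline age. A synthetic-data generator emulates the
    joint structure of patients, claims, and annotated clinical documents so
    the whole pipeline is testable end to end without access to protected
    health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
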