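Package: alftriage
Title: Diagnosis, Grading, and Outcome Prediction for Acute Liver Failure in Japan
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Japanese clinical decision stack for acute liver
    failure (ALF): hepatic-encephalopathy (coma) grading for adults (Inuyama
    1972) and children (5th Workshop on Pediatric Liver Diseases 1988), the
    2011 diagnostic criteria for ALF and late-onset hepatic failure (LOHF)
    with their etiology taxonomy and fulminant-hepatitis flag, the 1996
    two-step guideline for liver-transplant candidacy, and the 2011
    six-parameter prognostic scoring system with its mortality bands.
    Includes stratified cohort analytics that reproduce the 2010 nationwide
    survey aggregates from a packaged stratum-count table, a seeded synthetic
    cohort generator for property testing, confusion-matrix evaluation of
    death-call predictions, and ggplot2 visualisations. All functions take a
    data frame of patient records and return tibbles, so pipelines compose
    with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
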