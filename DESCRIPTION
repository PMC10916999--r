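Package: tapcog
Title: Keyboard-Tapping Motor Features and Cognitive Outcome Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing brief self-administered keyboard tapping tests
    as digital motor markers of cognitive performance in older adults. Reads
    raw key-press event logs, extracts four block-level motor features
    (tapping frequency, rhythm variability as the standard deviation of log
    inter-press intervals, key dwell time, and a weighted target-accuracy
    index), applies auditable cohort exclusion rules, and tests whether motor
    features improve prediction of count-valued cognitive test scores using
    exhaustive all-subsets negative-binomial (or Poisson/Gaussian) generalized
    linear models ranked by small-sample-corrected AIC, with delta-AIC
    equivalence sets. Includes a fully seeded synthetic-cohort generator that
    emulates the demographic, tapping and outcome structure of a community
    cohort study, so the whole pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
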