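Package: cncascade
Title: Copy-Number Breast-Cancer Subtype Classification with a Boosted-Tree Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies breast-cancer samples into the ten Integrative Cluster
    (IntClust) subtypes from DNA copy-number profiles alone. Class-average
    profiles are segmented with an exact penalized piecewise-constant fit, the
    breakpoint union across classes cuts the genome into shared feature
    regions, per-region mean copy number is scaled per cohort, intra-class
    outliers are removed with the local outlier factor, and labels are
    predicted by a six-class gradient-boosted model followed by pair-specific
    binary reclassification of four frequently confused subtype pairs.
    Includes SEG/probe-matrix/BED input and output, a full evaluation metric
    suite (per-class and micro/macro/weighted averages, multiclass Matthews
    correlation), a seeded synthetic-cohort generator emulating two profiling
    platforms, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
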