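Package: ecgaging
Title: ECG-Age Aging Effects and Cardiovascular Risk from Serial 12-Lead ECGs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying electrocardiographic aging effects: a seeded
    synthetic 12-lead ECG and longitudinal cohort simulator, signal-quality
    scoring and multi-lead consensus R-peak detection with beat segmentation,
    a differentiable surrogate ECG-age model with delta-age grouping and
    serial-consistency analysis, integrated-gradients relevance maps with
    beat-aligned aggregation and lead importance, clinical interval
    measurement (P, PR, QRS, QTc), and Kaplan-Meier, Cox proportional-hazards
    and logistic-regression risk estimation with a label-leakage guard for
    serial analyses. Tibble-first interfaces throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    signal,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
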