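Package: continuusparity
Title: Queen Life-History Demography for Lifelong Colony Census Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Life-table and fecundity-schedule analysis of lifelong weekly
    census data from single-queen ant colonies (Cardiocondyla obscurior
    style designs): mean-standardized (pace-corrected) mortality and
    fecundity trajectories, LOESS smoothing and landmark detection
    (fecundity peak, late-life sexual-investment peak, relative-mortality
    crossing), biomass-corrected caste-investment ratios with
    metabolic-exponent sweeps, sex ratios, lifetime production totals, and
    descriptive cohort statistics (Kendall tau-b, coefficients of
    variation, quartile summaries). Includes a generative cohort simulator
    ("continuusparity" model: continuous lifelong reproduction ending in
    reproductive death) with known ground truth for parameter-recovery
    testing, and a reproducible end-to-end pipeline.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
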