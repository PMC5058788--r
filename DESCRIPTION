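Package: markovcea
Title: Markov Cohort Cost-Effectiveness Analysis of Biologic Strategies in
    Metastatic Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tidyverse-native pipeline for three-state Markov cohort
    cost-effectiveness analysis of first-line biologic strategies
    (Cetuximab or Bevacizumab with chemotherapy backbones) in metastatic
    colorectal cancer. Converts median progression-free and overall
    survival into monthly transition probabilities, assembles per-cycle
    state costs from dosing arithmetic, adverse-event incidences and
    societal components, runs discounted cohort traces accumulating costs
    and quality-adjusted life-years, computes cost per QALY, incremental
    cost-effectiveness ratios and dominance classifications, and supports
    one-way deterministic sensitivity analysis (tornado) and seeded Monte
    Carlo microsimulation. Ships configuration fixtures encoding the
    published base case built on the CALGB 80405 trial, and a synthetic
    strategy generator with closed-form ground truth for testing.
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
    purrr,
    readr,
    rlang (>= 1.0.0),
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
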