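Package: pdl1hta
Title: Early Health Technology Assessment of Response-Predictive Biomarkers
    for Immunotherapy in Advanced NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic model for the early health technology
    assessment of biomarker tests that predict response to immunotherapy in
    advanced non-small-cell lung cancer. Decision trees stratified by tumour
    PD-L1 expression (<1%, 1-49%, >=50%) route patients to chemotherapy,
    immunotherapy or immunochemotherapy and feed a monthly-cycle Markov
    cohort model over a five-year horizon. The package computes discounted
    quality-adjusted life years and healthcare costs per strategy,
    incremental cost-effectiveness ratios with quadrant semantics against a
    willingness-to-pay/willingness-to-accept threshold, headroom analyses
    for a perfect test, sensitivity/specificity scenario grids and one-way
    deterministic sensitivity analyses. A seeded synthetic parameter
    generator emulates unavailable trial-level input tables, and an
    individual-level microsimulation provides an independent cross-check of
    the cohort engine.
License: MIT
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
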