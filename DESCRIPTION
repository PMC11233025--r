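Package: opioidits
Title: Interrupted Time Series Analysis of Opioid-Related Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-intervention interrupted time series (ITS)
    regression of monthly opioid-related death rates stratified by U.S.
    Census Region and gender. Parses CDC WONDER-dialect Multiple Cause of
    Death exports (including merging final and provisional extracts and
    small-cell suppression), applies the ICD-10 opioid inclusion rule to
    record-level death certificates, interpolates annual population
    estimates to monthly values, fits segmented linear regression models
    with immediate (level) and sustained (slope) intervention effects,
    projects a no-COVID-19 counterfactual, computes excess and cumulative
    excess opioid-related deaths, and attaches Poisson parametric bootstrap
    confidence intervals regionally and nationally. A synthetic-data module
    generates record-level certificates, monthly counts, and population
    tables from a known piecewise-linear truth so the full pipeline is
    testable without access to CDC WONDER.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    lubridate,
    withr,
    yaml,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
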