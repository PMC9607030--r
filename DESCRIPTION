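Package: mdaudit
Title: Auditing the Healthiness of Meal-Delivery-App Food Offerings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for auditing the food offerings of
    meal-delivery apps (MDAs) across a stratified sample of urban addresses.
    Provides a synthetic generator for small-area geography, street addresses,
    physical food-outlet locations and MDA menu snapshots; stratified address
    sampling by deprivation tertile, physical outlet-density tertile and
    ethnicity classification; a core/discretionary healthiness scoring scheme
    for menu items driven by an editable classification manual; a supervised
    text classifier with k-fold cross-validation that imitates the manual
    scoring; and equity analyses (score distributions, chi-square tests of
    healthy/unhealthy proportions by stratum, and outlet-availability quartile
    summaries).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
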