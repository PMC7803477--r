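Package: actipair
Title: Paired Comparison of Wearable-Tracker and Self-Reported Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing consumer wearable-tracker physical
    activity to questionnaire self-report and their associations with body
    mass index. Processes minute-level step counts into wear time, cadence
    based intensity classes and weekly activity summaries; cleans and scores
    IPAQ short-form responses into MET-hours per week; pairs device weeks
    with questionnaire recall windows and attaches anthropometry and
    covariates by proximity rules; and runs a comparative statistics suite
    of paired rank tests, rank correlations, nonparametric trend tests,
    cluster-robust linear regressions of BMI and Wald comparisons of
    device versus self-report coefficients. Includes a synthetic cohort
    generator with bout-structured step traces, recall-biased self-report
    and a configurable BMI outcome model so every stage is testable
    without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
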