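Package: ahcsflux
Title: Visit Duration Thresholds and Sampling Requirements for Automated
    Head Chamber Gas Flux Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing spot-sample gas flux records from
    automated head chamber systems (AHCS; e.g. GreenFeed) used with
    grazing and pen-fed cattle. Provides quality-control filtering of
    visit records (airflow adequacy and biologically infeasible flux
    ceilings), per-animal daily flux estimation for CO2, O2 and CH4 by
    arithmetic and time-bin averaging under visit-duration rules,
    method-agreement statistics (Pearson r, bias correction factor,
    Lin's concordance correlation coefficient, RMSE as a percent of a
    gold-standard mean), descriptive and agreement reports stratified
    by duration thresholds and ranges, a random visit-subsampling
    experiment that determines the minimum number of visits per animal
    achieving a concordance target, and a seeded synthetic AHCS cohort
    generator (trimodal diurnal visitation with minimum inter-visit
    gaps, right-skewed durations, duration-dependent capture bias,
    planted QC violations) so the whole pipeline is testable against
    known ground truth.
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
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
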