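Package: finlife
Title: State-Dependent Life-History Optimization for Fish in Ecosystem Size
    Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts optimal monthly allocation of stored energy to growth
    and reproduction for individual fish embedded in an ecosystem size
    spectrum. Prey intake and predation mortality are allometric functions of
    structural mass derived from size-spectrum theory; metabolic costs scale
    with mass and temperature following the metabolic theory of ecology. The
    optimal policy is obtained by backward-induction dynamic programming over
    a (length, stores, month) state space, and forward cohort simulation
    yields emergent growth curves, reproductive schedules, survivorship,
    lifespan and maximum body size under constant or seasonal environments,
    including scenario presets for three tuna ecological lifestyles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
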