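Package: devalsim
Title: Simulation and Analysis of Stopping-Induced Stimulus Devaluation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless, seedable simulator and analysis pipeline for a
    three-phase behavioral paradigm in which geometric shapes first acquire
    monetary value through an implicit reward schedule, are then paired with
    action stopping in a stop-signal task with an adaptive stop-signal-delay
    staircase, and are finally valued in a six-option auction. Provides
    reproducible trial-schedule generation, race-model agents with
    ex-Gaussian go and stop processes, mean-method SSRT estimation and
    race-model validity checks, knowledge classification from a simulated
    debrief, bidding-level dependent variables, mixed-design ANOVA with
    partial eta squared, tie-corrected and exact Wilcoxon signed-rank and
    Mann-Whitney tests, within-subject devaluation contrasts, bidding
    variance analyses, and Cook's-distance-screened correlation analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    jsonlite,
    rlang,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
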