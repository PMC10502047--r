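Package: ropscore
Title: Severity and Activity Scoring for Retinopathy of Prematurity Telemedicine Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scoring engines for retinopathy of prematurity (ROP) telemedicine
    screening programs. Implements a 0-100 telemedicine severity score built
    additively from ICROP zone, stage and plus-disease gradings (with
    regression, reactivation and aggressive-ROP handling, severity bands and a
    treatment-warranted flag) alongside a comparator 0-22 activity-scale
    lookup, a longitudinal exam-record data model with CSV readers and
    writers, a seeded synthetic NICU screening-cohort simulator, and the
    cohort-level comparison statistics used to contrast scoring systems:
    score-return rates, treatment-warranted identification accuracy, Spearman
    rank correlation, and AIC-based selection among linear mixed-effects
    trend models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
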