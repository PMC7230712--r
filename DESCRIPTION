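Package: chrononutr
Title: Chrononutrition Analysis of Meal Timing in Rotating Shift Workers
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize when shift workers eat. Builds timestamped
    intake events from photographic meal logs (merging same-type records
    within 15 minutes), classifies work periods into morning, evening and
    night shifts, constructs wake-to-wake analysis days anchored on the main
    sleep episode, and computes chrononutrition metrics: caloric intake
    standardized to the Mifflin-St Jeor basal metabolic rate and weighted by
    day length, first-meal latency, eating window, kcal-weighted circular
    mean intake times and dispersion (mean resultant length), night-time
    (2300-0600 h) and at-work caloric fractions, and 4-h clock-time and
    time-awake caloric distributions. Includes the statistical layer used
    for day-type comparisons (chi-square goodness of fit, Welch's t,
    Watson-Williams circular ANOVA, linear mixed-effects models with
    pairwise contrasts, Benjamini-Hochberg adjustment) and a synthetic
    shift-roster data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
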