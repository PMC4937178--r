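Package: cardiofit
Title: Heart-Rate-Reserve Exercise Prescription and Beats-in-Zone Training Load
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for heart-rate-based exercise prescription and training-load
    tracking. Computes Karvonen (heart-rate-reserve) target heart rates and
    ACSM-style FITT prescriptions from configurable fitness-classification
    tables; quantifies training load as "mBeats", the number of heart beats
    accumulated inside a personalized heart-rate zone, with adaptive
    weekly-to-daily target redistribution; scores two submaximal fitness tests
    (the Ruffier-Dickson squat test and the Ebbeling single-stage treadmill
    walk); simulates physiologically plausible second-by-second heart-rate
    streams, test sessions and pre/post intervention cohorts with known ground
    truth; and analyses cohort tables with split-plot (mixed) ANOVA including
    Greenhouse-Geisser and Huynh-Feldt sphericity corrections, Tukey HSD
    post-hoc comparisons and Pearson correlation. All user-facing functions
    take and return tidy tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
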