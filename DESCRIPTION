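Package: pushrim
Title: Pushrim Kinetics and Push-Phase Analysis for Instrumented
    Wheelchair Wheels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for handrim force/moment/angle recordings
    from instrumented wheelchair wheels (SmartWheel-like, 240 Hz): dynamic
    offset correction, Savitzky-Golay wheel-velocity estimation, force-
    threshold push segmentation, per-push kinetic and spatio-temporal
    parameters (peak total force, peak propulsive moment, rate of rise,
    fraction of effective force, peak power, angular impulse, push/cycle
    time, push angle), and the within-subject 2x2 statistical comparison
    used in racket-sport propulsion studies (repeated-measures ANOVA with
    partial eta-squared, paired t tests, pooled-SD Cohen's d, Bonferroni
    adjustment). Includes a synthetic signal generator with closed-form
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
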