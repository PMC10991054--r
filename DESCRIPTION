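Package: gazecue
Title: Simulation and Psychometrics for a Browser-Based Gaze-Understanding Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator and psychometrics toolkit for a
    gaze-cueing search task in which an animated agent's eye direction
    cues the landing position of a hidden target. Provides scene
    geometry in normalized viewport coordinates with forward gaze
    posing and ideal-observer inversion, constrained randomization of
    trial sequences (balanced categories, bounded run lengths, fixed
    retest sequences), a synthetic-participant simulator with
    age-graded angular gaze noise, outcome scoring (click imprecision
    in target widths; box-choice accuracy), split-half reliability
    estimators (first-second, odd-even, permutated, Monte Carlo, with
    optional stratification by target position) with Spearman-Brown
    correction, hierarchical test-retest reliability via random-slope
    mixed models, and lognormal / Bernoulli-logit developmental
    trajectory models, together with a JSON session format and tidy
    CSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
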