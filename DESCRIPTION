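Package: apparency
Title: Auditory Signal Noticeability from Heart-Rate Orienting Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how noticeable short auditory signals are
    under realistic background noise, using the cardiac orienting response.
    Event-locked five-beat RR-interval windows around each stimulus onset are
    summarised by an orienting-response (OR) statistic, classified as heart-rate
    acceleration or deceleration at a +/-2 threshold, and aggregated into
    per-participant, per-sound "apparency" scores (the proportion of valid
    presentations eliciting a marked response). Includes two-period crossover
    reproducibility screening of sounds via Welch carryover and period-effect
    tests, randomized-trial analyses (intention-to-treat median imputation,
    one-way ANOVA with eta-squared, diurnal paired t-tests with Cohen's d_z,
    pooled acceleration/deceleration response ratios), and a synthetic-data
    generator that emulates the full three-day, two-period stimulus protocol
    and RR-interval streams with injectable responses and missingness, so the
    entire pipeline is testable end to end without physiological recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
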