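Package: chronomr
Title: Time-Resolved Mendelian Randomization with Additive Hazards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the cumulative (life-course) effect of a sustained
    exposure on disease hazard at every age, using a genetic instrument whose
    effect on the exposure varies with age.  The instrument effect on outcome
    is estimated non-parametrically with Aalen's additive hazards model, its
    yearly increments are converted to momentaneous exposure effects through
    age-resolved Wald ratios, and these are integrated (midpoint or trapezoid
    rule) into the cumulative effect with delta-method variances.  Includes
    kernel local-linear and Hodrick-Prescott trend estimation with parametric
    bootstrap bands, Steiger directionality filtering, cross-fitted polygenic
    score construction, a probit resampling correction for age-dependent
    selection, and a synthetic cohort generator for validation under a known
    time-varying generative model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
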