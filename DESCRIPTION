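Package: pupilphase
Title: Pupil Size Dynamics over the Respiratory Cycle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the pupillary respiratory-phase response:
    staged cleaning of eye-tracker pupil traces (validity rules, blink
    interpolation with range guards, outlier masking, session exclusion, eye
    averaging, z-scoring), airflow-based respiratory phase estimation
    (landmark detection and piecewise-linear 0-360 degree phase), phase-binned
    pupil statistics with a sign-flip maximum-statistic permutation test,
    weighted circular summaries with the Rayleigh test, repeated-measures
    ANOVA with Mauchly's test and Greenhouse-Geisser correction (Friedman
    fallback), and a synthetic-recording generator with full ground truth for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
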