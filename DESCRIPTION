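Package: actipred
Title: Forecasting Cognitive Decline from Free-Living Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Turns free-living accelerometer recordings (raw 30 Hz tri-axial
    hip data or 15-second wrist activity-count epochs) into minute-level
    ENMO, counts-per-minute and vector-magnitude-count signals, extracts a
    98-measure bank of statistical and circadian-harmonic features, and
    trains tiered gradient-boosted classifiers that forecast binary
    cognitive decline (a drop in the Montreal Cognitive Assessment score
    between baseline and follow-up). Includes a device-faithful synthetic
    cohort generator so the full pipeline is testable without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
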