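Package: panometry
Title: FLIP Panometry Esophageal Motility Classification and HRM Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based classification of esophageal motility from functional
    lumen imaging probe (FLIP) panometry under the v2.0 (Dallas consensus) and
    v1.0 schemes, together with the supporting toolchain: a synthetic FLIP
    diameter-topography simulator with known contractile-response and
    esophagogastric-junction (EGJ) opening phenotypes, feature extraction
    (EGJ distensibility index, maximum EGJ diameter, contraction-event
    detection in time-by-sensor diameter grids), adjudication of Chicago
    Classification v4.0 manometry labels against integrated relaxation
    pressure thresholds and timed barium esophagram rules, calibrated
    synthetic cohort generation, and diagnostic concordance analysis
    (cross-tabulation, within-class proportions, predictive values, and
    scheme-version reclassification tables).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
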