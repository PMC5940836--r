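Package: ppgbp
Title: Cuffless Blood Pressure Estimation from Photoplethysmogram Heart
    Rate and Pulse Volume
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates mean arterial, systolic and diastolic blood pressure
    from a single finger photoplethysmogram (PPG) without a cuff. Detects
    pulse feet on the waveform, extracts beat-by-beat heart rate and the
    modified normalized pulse volume (mNPV, the AC/DC amplitude ratio of
    the PPG), rejects outlying beats with a sliding-window standard
    deviation rule, averages over 45-second blocks, and calibrates the
    log-linear model ln BP = a ln HR + b ln mNPV + c against reference cuff
    readings. Includes method-comparison analytics (geometric mean
    regression, Bland-Altman analysis, paired effect sizes), synthetic PPG
    waveform and calibration-cohort generators with known ground truth, and
    a command-line interface for the full pipeline.
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
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
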