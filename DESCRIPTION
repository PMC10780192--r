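Package: raidose
Title: Blood-Dose-Limited Radioiodine Therapy Dosimetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for I-131 radioiodine therapy dosimetry on the
    Benua-Leeper blood-dose-limited model: conjugate-view and well-counter
    count reduction, mono-/bi-exponential clearance fitting,
    time-integrated activity coefficients, the 2 Gy blood-dose and 48 h
    retention-capped maximum permissible activity (MPA), a calibrated
    synthetic patient-biokinetics simulator, an abbreviated-protocol
    (4/24/48 h) neural-network MPA predictor, and paired agreement
    statistics for validating abbreviated protocols against the full
    multi-day protocol.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
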