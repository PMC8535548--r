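Package: pqrst
Title: PQRST Fiducial-Point Delineation of Single-Lead ECG via Adaptive
    Bilateral Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the eleven fiducial points of the ECG PQRST complex
    (P-onset, P, P-offset, Q-onset, Q, R, S, S-offset, T-onset, T, T-offset)
    from single-lead sample streams. A variance-adaptive one-dimensional
    bilateral filter predicts the QRS-free background signal; R-peaks,
    their polarity and fragmented (notched) R-waves are found from the
    enhanced residual, and the remaining fiducials are delineated with
    slope predicates and symmetric and asymmetric point filters, including
    mapping of undetected points. Includes sliding-window processing with
    seam stitching, time- and frequency-domain heart-rate-variability
    metrics, ST/PR/QT interval trends, detection and delineation
    evaluation metrics, and a synthetic ECG generator with exact
    ground-truth fiducials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    graphics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    utils,
    tibble,
    tidyr
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
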