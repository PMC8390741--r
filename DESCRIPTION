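Package: prrtdose
Title: Absorbed-Dose Calculation and Single-Time-Point Prediction for Lu-177 PRRT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Internal dosimetry for peptide receptor radionuclide therapy (PRRT)
    with [177Lu]-DOTA-TATE. Implements the standard multi-time-point MIRD
    workflow (mono-exponential time-activity fitting, cumulated activities,
    organ/tumor dose from dose-factor tables, blood-based bone-marrow dose), a
    trained log-log multiple linear regression model that estimates absorbed
    dose from a single post-therapy SPECT/CT study, treatment-continuation
    logic driven by cumulative-dose safety thresholds (25 Gy kidneys, 2 Gy
    bone marrow), a synthetic patient-cohort generator with known ground
    truth, and agreement statistics (relative differences, Bland-Altman
    limits, Pearson correlation, one-sided binomial power).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
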