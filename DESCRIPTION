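Package: tegcut
Title: Early Prediction of Thromboelastography Clot Strength from Reaction Time
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the inverse relationship between the earliest available
    thromboelastography (TEG6s) parameter, the citrated rapid TEG reaction
    time (CRT-R), and final clot-strength parameters (maximum amplitude, MA)
    using exponential-decay regression; derives clinically anchored CRT-R
    cutoffs by inverting the fitted curve at MA targets, with bootstrap
    percentile confidence intervals; evaluates those cutoffs as binary
    classifiers (sensitivity, specificity, predictive values, accuracy);
    converts between CRT-R and TEG activated clotting time scales; and
    simulates synthetic paired-measurement cohorts with the statistical
    structure the analysis assumes, so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
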