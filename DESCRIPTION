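Package: filmsense
Title: Psychophysiological Characterization of Caffeine Oral Films from
    Multimodal Signal Energy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for characterizing the
    release profile of caffeine oral films from autonomic signals.
    Generates synthetic cohorts of electrocardiogram, electrodermal
    activity and respiration recordings with a pharmacokinetically
    shaped caffeine effect, preprocesses them with linear-phase FIR
    filters and amplitude normalization, extracts windowed signal-energy
    features over five-minute segments, and discriminates caffeine from
    placebo sessions with a bank of binary classifiers under
    leave-one-out cross-validation, including an ROC-threshold
    classifier.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    MASS,
    rpart,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
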