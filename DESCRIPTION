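Package: flockfusion
Title: Multimodal Image-Tabular Fusion Regression for Livestock Live Weight
    and Carcass Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sheep live weight, carcass weight, fat mass and lean
    mass from paired dorsal/lateral photographs combined with tabular body
    condition records. Implements three hybrid fusion architectures (a
    feature-concatenation baseline, a CBAM plus cross-modal-attention fusion
    network, and a Vision-Transformer-style token-level fusion regressor)
    trained with a homoscedastic task-uncertainty multi-task loss, together
    with animal-level partitioning and cross-validation, an augmentation
    suite with leakage checks, agreement statistics (Lin's concordance
    correlation, Bland-Altman limits, paired tests), Grad-CAM explainability
    for regression outputs, and a calibrated synthetic flock generator that
    renders images whose geometry encodes the ground-truth traits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml,
    jsonlite,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
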