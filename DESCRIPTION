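Package: riseqc
Title: Artifact Detection and Severity Grading for Fetal MRI Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality assurance for 2D fetal magnetic-resonance slices. A pair
    of convolutional networks built from stacked residual-inception
    squeeze-and-excitation (RISE) blocks detects which artifact types
    (motion, chemical shift, radio-frequency) degrade a slice and regresses
    each artifact's severity; the two outputs are combined into a graded
    report (None/Mild/Medium/Severe). Ships a synthetic phantom and k-space
    artifact simulator with known labels so the whole pipeline is testable
    without clinical data, plus preprocessing (mask overlay, max-intensity
    normalization, resizing, 80:10:10 splitting, minority up-sampling),
    training with Adam and k-fold cross-validation, and multi-label
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    EBImage,
    yaml,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
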