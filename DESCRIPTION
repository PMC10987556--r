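Package: handjoint
Title: Ensemble Detection of Finger-Joint Regions and Special Findings in
    Hand Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates proximal interphalangeal (PIP/IP) and metacarpophalangeal
    (MP) finger-joint regions in hand radiographs and classifies two
    high-impact radiographic findings of rheumatoid arthritis, ankylosis and
    subluxation/dislocation, with a two-detector ensemble of anchor-box
    (multibox) detectors. Provides box geometry and offset encoding, a small
    trainable convolutional detector with the multibox localisation and
    confidence losses, sliding-window tiled inference with non-maximum
    suppression, the cross-detector box-fusion ensemble, stratified five-fold
    evaluation with detection-rate and confusion-matrix metrics, Grad-CAM
    contribution maps, and a synthetic hand-phantom generator that emulates
    the study conditions for desk-scale experiments.
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
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
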