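Package: qselast
Title: Quasi-Static Ultrasound Elastography with 2D Multiresolution
    Hybrid Displacement Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Strain imaging for quasi-static ultrasound elastography.
    Implements a 2D multiresolution hybrid displacement estimator
    (three-level normalized cross-correlation block matching on
    multirate envelope pyramids feeding a lateral-shift-compensated
    phase zero-crossing Newton refinement), the original chained 1D
    phase zero-crossing estimator and its downsampled-baseband variant
    as baselines, least-squares strain reconstruction, and
    elastographic quality metrics (CNRe, strain ratio, inclusion area
    ratio).  Ships a self-contained inclusion-phantom simulator: a
    plane-strain finite-element solver for ground-truth displacement
    and strain fields plus a convolution-model RF synthesizer, so the
    full estimator comparison study can be reproduced on a desktop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    signal,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
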