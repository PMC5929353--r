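Package: braggscreen
Title: Convolutional Screening of Serial Crystallography Diffraction Frames
Version: 0.1.0
Authors@R:
    person("braggscreen", "developers", email = "braggscreen@example.org",
           role = c("aut", "cre"))
Description: Tools for vetoing blank shots in serial femtosecond
    crystallography. Provides a synthetic diffraction-frame simulator with
    known ground-truth Bragg spot counts, image conditioning (photon-
    preserving binning, cropping, augmentation, global and local contrast
    normalization), a threshold-based spotfinder baseline, a compact
    convolutional neural network classifier producing Hit/Maybe/Miss
    probabilities (trained by class-balanced mini-batch gradient descent on
    cross-entropy), and evaluation utilities (confusion matrices, screening
    success rates, confidence histograms, input-gradient saliency maps and
    cross-dataset / data-size / preprocessing-ablation experiment drivers).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
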