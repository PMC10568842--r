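Package: octapseudo
Title: Pseudoaveraging of Enface OCT Angiography Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, registration, averaging and learned denoising
    ("pseudoaveraging") of 2-D enface optical coherence tomography
    angiography (OCTA) scans. Generates seeded synthetic retinal-vasculature
    phantoms with speckle, decorrelation background noise, motion-line
    artifacts, shadowing and diabetic-retinopathy-like lesions; registers and
    averages repeated frames; trains a patch-based 5-level U-Net with a
    masked L1 loss and stochastic gradient descent to map single-frame scans
    to multi-frame-average quality; and evaluates quality gains and
    perfusion-artifact safety (false-negative/false-positive perfusion)
    against the synthetic ground truth, including exact Wilcoxon
    signed-rank comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
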