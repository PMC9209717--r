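Package: pcseg
Title: Semi-Automatic Closed-Contour Segmentation with Principal Curves
    and an Evolution-Initialized Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage semi-automatic delineation of closed organ
    boundaries (such as the prostate in transrectal ultrasound) from a
    handful of user-supplied seed points.  Stage one fits a constrained
    closed polygonal principal curve to the seed points and emits an
    ordered vertex sequence; stage two trains a one-hidden-layer neural
    network with an adaptive learning rate, initialized by an improved
    differential-evolution search, to turn that sequence into a smooth,
    closed, interpretable parametric contour.  Includes polygon
    rasterization, Dice/Jaccard/accuracy overlap metrics, a curve-to-data
    distance, a synthetic generator of star-shaped ground-truth contours
    and radiologist-like seed points, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
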