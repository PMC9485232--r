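Package: finscale
Title: Stereo-Parallax Morphometry for Farmed Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating fish standard length and weight from
    stereo image annotations using the parallax (disparity) of paired
    landmarks. Includes a pinhole stereo-rig model with Brown radial
    distortion, an empirical chessboard calibration that maps landmark
    translation (pixels) to a micron-per-pixel scale via polynomial ridge
    regression, quality-controlled length estimation from snout and caudal
    landmarks, allometric length-weight modelling (W = a * L^b),
    size-distribution comparison statistics (Shapiro-Wilk, Levene, Welch,
    q-q pairs, 1-cm histograms), and seed-deterministic synthetic scene
    generators that emulate a buoy-mounted vertical stereo rig for
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
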