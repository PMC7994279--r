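Package: speckletrack
Title: Normalized Cross-Correlation Speckle Tracking for Diaphragm
    Deformation Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates diaphragm motion and deformation from B-mode
    ultrasound cine loops by normalized cross-correlation (NCC) block
    matching with lateral interpolation of both the image lines and the
    correlation surface. Interframe displacement fields are accumulated
    into continuous Lagrangian material-point trajectories, cumulative
    curves are drift-corrected over the breathing period, and global
    strain is computed as the relative change in length of a
    user-supplied region-of-interest polyline. A synthetic
    speckle-phantom generator with analytically known motion provides
    ground truth for validation. Readers are included for multi-frame
    DICOM cine loops and multi-page TIFF fixture stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
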