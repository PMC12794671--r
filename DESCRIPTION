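Package: spermtrackr
Title: Computer-Vision Analysis of Sperm Concentration, Motility and Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Open computer-aided sperm analysis (CASA) from grayscale
    microscopy video. Detects sperm-head centroids as high-contrast corners,
    tracks them with a pyramidal Lucas-Kanade optical-flow tracker with
    forward-backward consistency checks, and computes the standard kinematic
    parameters per cell (VSL, VCL, VAP, LIN, ALH_max, BCF) in physical
    units. Cells are graded into WHO 6th-edition motility categories and
    sample concentration is estimated through a count-to-concentration
    calibration line. Method-agreement statistics (linear calibration
    against a reference tracker, R-squared/RMSE/MAE, Bland-Altman limits of
    agreement, duplicate-measurement repeatability) and a synthetic video
    simulator with analytically known ground truth support validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
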