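Package: femoffset
Title: Radiographic Femoral Offset Measurement and Rotation-Sweep Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based measurement of femoral offset from calibrated
    radiographs: total-least-squares cortical line fits, bisector shaft axis,
    least-squares head-circle fit with geometric refinement, calibration-sphere
    scaling, and perpendicular offset in millimetres. Includes a synthetic
    orthographic-projection simulator of the proximal femur for parameter-
    recovery studies, per-specimen rotation-sweep analysis (true vs. aligned
    offset, underestimation, rotation at maximum), and intrarater reliability
    via the two-way random-effects absolute-agreement single-measures
    intraclass correlation coefficient ICC(2,1) with nonparametric bootstrap
    confidence intervals.
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
    purrr,
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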