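Package: spinehough
Title: Hough-Transform Segmentation and FDG-PET Quantification of the
    Spinal Cord on Whole-Body PET/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Operator-independent extraction of the spinal canal and spinal
    cord from coregistered whole-body CT/PET volumes.  On each axial CT
    slice a generalized Hough transform detects the spinal canal as a
    two-parameter curve with three convexities and the cord as a
    four-parameter ellipse; binary masks built from the fitted curves
    extract the coregistered PET radioactivity, from which per-segment
    standardized uptake values (SUV), liver-normalized SUVs (NSUV), the
    volume-weighted whole-cord NSUV and canal/cord volumes are computed.
    Includes a synthetic digital-phantom generator with analytic ground
    truth, cohort-level summary statistics (fifth-decile dichotomization,
    mortality-rate contingency arithmetic, group comparison), NIfTI input
    and output, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    generics,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
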