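Package: penetromech
Title: Cell Penetration Mechanics from Microscopy Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying oocyte deformation and intracellular stress
    during micropipette penetration. Generates synthetic penetration image
    sequences with exact ground-truth contours, detects cell deformation
    parameters (bounding-box width reduction and invaginate value) from
    grayscale image sequences via Hough circle localization, Canny edge
    detection and morphological contour extraction, evaluates the point-load
    membrane force model and an empirical intracellular-stress model
    F = alpha1 * r^beta * d^3, and fits the model's coefficients by two-stage
    and joint nonlinear least squares with goodness-of-fit and Pearson
    validation of deformation curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
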