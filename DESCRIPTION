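Package: seedmorph
Title: Seed Morphometrics and Counting from RGB Images
Version: 1.0.0
Authors@R:
    person("Seedmorph", "Developers", email = "seedmorph@example.org",
           role = c("aut", "cre"))
Description: Measures seed length, width, projected area, and aspect ratio
    from RGB photographs of seeds on a dark background, and counts seeds per
    image. The pipeline follows the classical fixed-threshold approach:
    grayscale conversion, optional morphological dilation, global binary
    thresholding, contour extraction with maximum-area selection, and
    minimum-area bounding rectangles. Pixel measurements are converted to
    millimetres via a two-point ruler calibration. Includes method-comparison
    statistics (RMSE, MAE, residual standard error, percent errors, linear
    fit), a ground-truth synthetic scene generator for fully self-contained
    testing, and a command-line interface. Image I/O (PNG, PGM/PPM,
    uncompressed TIFF) is implemented natively so the package has no external
    imaging dependencies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    optparse,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
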