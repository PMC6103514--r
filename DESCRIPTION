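Package: canopyN
Title: Foliar Nitrogen Prediction from Field Canopy Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts foliar total nitrogen content of sandalwood (Santalum
    album) saplings from ground-based field photographs. Implements a
    CIELAB-channel Otsu segmentation cascade that separates the target plant
    from soil, weeds and darker neighbouring plants; growth-status indicators
    defined as the ratio of plant pixels to the pixel count of the minimum
    enclosing rectangle or minimum circumscribed circle; per-sample colour
    features (RGB, HSI, Lab and mixed-system channel means); five parametric
    prediction-model families with a growth-status intercept term; and
    parameter estimation by both nonlinear least squares and an
    errors-in-variables (measurement-error) estimator. Includes a seeded
    synthetic scene and sample-table generator with known ground truth for
    testing, evaluation statistics, and multi-criteria model ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    readr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
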