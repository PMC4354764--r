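Package: ticcad
Title: Semi-Automatic Kinetic Analysis of Breast DCE-MRI Time-Intensity Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided analysis of single-slice dynamic contrast-enhanced
    breast MRI. Segments a mass-like lesion inside a user-drawn region of
    interest (subtraction image, region-constrained Otsu thresholding, 4x4
    morphological opening, largest eight-connected component), computes six
    semi-quantitative kinetic parameters (signal-intensity slope, maximum
    slope of increase, initial/peak/second enhancement percentages, early
    signal enhancement ratio) from the mean time-intensity curve and per
    pixel, classifies curves as persistent (type I), plateau (type II) or
    washout (type III), and evaluates benign/malignant discrimination by ROC
    analysis with DeLong standard errors and Youden-optimal cutoffs. Includes
    a seeded digital phantom generator producing dynamic series with
    mass-like enhancing lesions for testing and simulation studies.
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
    pROC,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
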