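Package: exmqc
Title: Quantitative Validation of Expansion Microscopy Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to validate expansion-microscopy experiments quantitatively:
    estimation of the expansion factor from paired pre-/post-expansion
    landmarks via a closed-form least-squares similarity transform,
    quantification of nonrigid expansion distortion as measurement error
    versus measurement length from a demons-type displacement field, and
    detection, Gaussian-fit FWHM sizing and density-based clustering of
    sub-diffraction puncta in 2D and 3D super-resolution image volumes.
    Includes a synthetic-data generator that plants known transforms,
    distortion fields and punctum parameters so every pipeline stage can be
    checked against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    tiff,
    minpack.lm,
    EBImage,
    generics,
    ggplot2,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    withr
Config/testthat/edition: 3
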