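Package: corvib
Title: Corneal Vibration Analysis for Air-Puff Tonometry Image Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures four types of corneal vibration from high-speed
    Scheimpflug image sequences recorded during air-puff intraocular
    pressure measurement. Extracts the outer corneal contour with
    sub-pixel precision, separates eyeball reaction and corneal
    deformation, splits the deformation into frequency bands, locates the
    two applanation instants, and computes peak, quarter,
    maximum-deformation and cutoff vibration traces with per-frame error
    bounds, vibration angles and spectral summaries. A ground-truthed
    phantom generator renders synthetic deformation sequences so the
    whole pipeline can be validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
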