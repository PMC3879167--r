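Package: chromopin
Title: Colorimetric Quantification and Hit Calling for Pinned Colony-Array Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of chromogenic colony-array screens on
    indicator agar, built around the CPRG (chlorophenyl
    red-beta-D-galactopyranoside) envelope-integrity assay for ordered
    bacterial deletion libraries. Provides a synthetic plate-image generator
    with exact ground truth, grid fitting and colony segmentation for 384- and
    1536-pin arrays, per-pixel HSV hue scoring of colony redness,
    replicate-averaged score matrices with threshold hit calling,
    cross-condition hit comparison, hypergeometric term enrichment, and
    genetic-interaction growth scoring from double-mutant colony sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    jsonlite,
    withr,
    EBImage,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
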