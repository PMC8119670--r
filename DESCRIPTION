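Package: stainfree
Title: Stain-Free Live/Dead Cell Classification from Bright-Field Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A weakly supervised pipeline for classifying adherent cancer
    cells as live or dead from bright-field microscopy alone. Paired
    fluorescence images (propidium iodide) provide patch-level weak labels
    through a two-component Gaussian mixture threshold rule; empty or
    out-of-focus patches are rejected with deep features and a support
    vector machine; a small convolutional network is trained on
    bright-field patches with imbalance-corrected sampling; and the fitted
    classifier is inspected through penultimate-layer embeddings and
    gradient-weighted class activation maps. A synthetic paired-image
    generator reproduces the statistical structure the analysis assumes,
    so the whole pipeline is testable without any real image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    tiff,
    e1071,
    Rtsne,
    EBImage,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    cluster,
    purrr
Config/testthat/edition: 3
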