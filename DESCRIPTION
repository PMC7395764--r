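Package: lactuca
Title: Nondestructive Estimation of Lettuce Growth Traits from Top-View Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates growth-related traits of greenhouse lettuce (leaf fresh
    weight, leaf dry weight, leaf area) nondestructively from top-view RGB
    images with a multi-output convolutional regressor, and compares it against
    classical pipelines: support-vector and random-forest regression on
    handcrafted colour/texture/shape features, and univariate linear models on
    depth-derived structural traits (canopy height, projected area, digital
    volume). Includes a synthetic rosette-scene generator with analytic
    ground-truth traits so the full pipeline is testable end to end, an
    image-augmentation scheme for greenhouse illumination, stratified dataset
    partitioning, and an R-squared/NRMSE evaluation layer with per-cultivar and
    cross-season reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
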