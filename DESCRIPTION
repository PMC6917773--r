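Package: mphisto
Title: Label-Free Multiphoton Virtual Histology Classification with Physics-Based Domain Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tile-based deep-learning classification of multimodal multiphoton
    virtual-histology slides (THG, NADH, SHG, FAD channels) as cancer versus
    normal. Provides a synthetic-cohort simulator with ground-truth object
    geometry, U-Net-style adipocyte segmentation with the tile-retention rule,
    a physics-based image-degradation model (point-spread-function blur,
    ambient-light noise, vibration jitter, downsampling) for adapting a
    classifier trained on high-quality bench data to lower-quality
    intraoperative data, subject-disjoint training of a ResNet-20-style
    classifier on a built-in CPU CNN engine, slide-level heatmap aggregation
    with ROC/AUC statistics, and interpretability via class activation mapping
    and t-SNE feature canvases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    tiff,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
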