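Package: ctprob
Title: Threshold and Probabilistic Classification of Ischemic Regions on CT Perfusion Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare single-parameter threshold classification with
    multivariable logistic probability-map classification of ischemic stroke
    regions on CT-perfusion (CTP) parameter maps. Includes a digital CTP
    phantom and cohort generator with known tissue classes, block-circulant
    SVD deconvolution of 4D CTP series into CBF, CBV, MTT and TTP maps,
    ROC/Youden threshold training, voxelwise logistic probability models,
    morphology-cleaned and hemisphere-difference volumetry, and
    precision-recall and volume-difference evaluation of both classification
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
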