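Package: noduleablate
Title: Information Ablation for Lung Nodule Malignancy Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how much of an image-based lung nodule
    malignancy classifier's performance is attributable to the predictors of
    the Brock logistic risk model. Provides automated nodule sizing from
    binary segmentation masks (volume, equivalent spherical diameter, and two
    maximal axial diameter estimators), the Brock risk model with
    feature-reduced variants, three volumetric image-ablation operators
    (parenchyma-only translation, uniform-density replacement, and
    volume-preserving sphere implantation), a fixed-feature surrogate risk
    classifier evaluated under a participant-level stratified k-fold
    protocol, and paired AUC comparison by bootstrap confidence intervals and
    permutation tests. A synthetic CT-nodule cohort generator with known
    generative structure supports end-to-end validation of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    grDevices,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
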