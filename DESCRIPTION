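Package: stackpcr
Title: Stacked Sparse Principal Component Regression for Multimodal Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-level stacked generalization for predicting a continuous
    phenotype from several high-dimensional feature channels (neuroimaging
    modalities such as functional connectivity, cortical thickness, surface
    area, volumetric features and local connectome vectors). Level one fits
    an L1-penalized principal component regression (LASSO-PCR) per channel
    with inner cross-validated penalty selection and produces out-of-fold
    training predictions; level two re-learns a non-negative L1 meta-model
    over the stacked channel predictions. Includes family-aware Monte Carlo
    cross-validation, train-only confound residualization, a confounder
    channel, percentile-bootstrap summaries of median performance, paired
    channel comparisons, decoding-to-encoding weight transformation, and a
    synthetic multimodal cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
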