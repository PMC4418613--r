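Package: thymoshape
Title: 3D Shape Analysis of Segmented Tumors and Invasiveness Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes quantitative 3D shape features (volume, surface area,
    sphericity, discrete compactness, 3D roundness) from binary segmentation
    masks with physical voxel spacing, and provides the downstream
    discrimination pipeline used in CT radiomics studies of tumor
    invasiveness: univariate screening, backward-stepwise binary logistic
    regression with likelihood-ratio removal, leave-one-out cross-validated
    ROC analysis with DeLong comparison of correlated AUCs, inter-rater
    agreement via two-way random-effects absolute-agreement intraclass
    correlation, and Fisher-z sample-size calculation. Includes a synthetic
    generator for digital tumor phantoms with controllable lobulation and for
    two-class cohorts, so the full pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
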