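Package: nogrownet
Title: Multi-Task Prediction of Pulmonary Nodule Growth from Baseline CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Predicts the follow-up appearance of a pulmonary nodule from a
    single baseline CT volume of interest, conditioned on the follow-up
    interval. A shared 3D convolutional encoder with a sinusoidal temporal
    encoding feeds three task decoders that jointly learn a dense
    displacement field (shape and volume change), a texture residual
    (density change) and a segmentation mask; predictions fuse the warped
    baseline with the masked residual. Includes NIfTI volume preprocessing,
    local normalized cross-correlation, Tversky and Dice objectives,
    PSNR/SSIM/DSC evaluation with nodule-region variants, two-stage training
    with patient-level cross-validation, and a synthetic longitudinal nodule
    phantom generator with known growth ground truth for desk-scale
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
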