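Package: augreg
Title: Deformable Image Registration with an Augmented-Regularization Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised deformable registration of 2D and 3D grayscale
    volumes with dense displacement fields. A VoxelMorph-style registration
    network is trained jointly with a successive "augmented" network whose
    predicted field is penalized toward zero, and optionally with an
    adversarial discriminator; at inference only the registration network is
    used. Includes dense-field warping and composition, local normalized
    cross-correlation and smoothness losses, multi-tissue synthetic phantoms
    with ground-truth deformations, Dice/SSIM/PCC evaluation, and NIfTI
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
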