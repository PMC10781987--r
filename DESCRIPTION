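Package: glomopaint
Title: Inpainting-Based Data Augmentation and Segmentation for Sclerosed Glomeruli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for augmenting kidney-biopsy training data by mask-conditioned
    generative inpainting of globally sclerosed glomeruli, and for training an
    encoder-decoder network that segments normal and sclerosed glomeruli in
    whole-slide image tiles. Includes slide preprocessing (downsampling,
    annotation rasterization, overlapped tiling, centred glomerulus crops), a
    DCGAN-based binary-mask synthesizer with morphological post-processing, an
    attention-gated inpainting generator with global and local patch
    discriminators, the full composite loss (adversarial, pixel, perceptual,
    style), a test-phase synthesis pipeline that pastes generated glomeruli into
    regions of interest, segmentation training with combined cross-entropy and
    Dice loss, pixel-level evaluation metrics (precision, recall, F1, Dice, MAE,
    PSNR, SSIM), and a deterministic synthetic-histology fixture generator. All
    networks run on a small self-contained reverse-mode autodiff engine with
    compiled convolution kernels, so the whole pipeline is testable on a single
    CPU without external model weights.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
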