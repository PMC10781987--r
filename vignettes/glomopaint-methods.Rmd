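---
title: "Methods: inpainting-based augmentation and segmentation of sclerosed glomeruli"
author: "glomopaint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inpainting-based augmentation and segmentation of sclerosed glomeruli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Percent global glomerulosclerosis — the fraction of glomeruli that are fully
scarred — is a key criterion when a donor kidney is evaluated for
transplantation. Deep segmentation networks can find and classify glomeruli
in whole-slide images (WSIs), but public kidney datasets contain far fewer
sclerosed than normal glomeruli, and that class imbalance hurts exactly the
class that matters most. `glomopaint` implements a data-augmentation remedy:
synthesize new sclerosed glomeruli *in place* in real tissue by
mask-conditioned generative inpainting, then train the segmenter on the mix
of real and synthesized tiles.

## Pipeline overview

1. **Slide preparation** (`downsampleSlide`, `rasterizeAnnotations`,
   `tileWithOverlap`, `extractGlomCrop`). Slides are downsampled 2x (area
   interpolation), annotations become per-class binary masks, and rasters
   are cut into 1024x1024 tiles with stride 512. For the inpainting
   training set, each sclerosed glomerulus is cropped to a 256x256 window
   centred on the centre of the **minimum enclosing circle** of its outline
   (Welzl's algorithm, exact), so the glomerulus sits centrally in the crop.
2. **Inpainting network** (`buildGenerator`, `buildDiscriminator`). The
   generator input is the 4-channel stack of the gap image
   `Xgap = Xori * (1 - Xmask)` and the mask. Its encoder is a 7x7
   convolution followed by two 4x4 stride-2 convolutions; then eight AOT
   blocks, a self-attention block operating on the quarter-resolution
   (64x64 for 256 inputs) feature map, and a mirrored decoder with skip
   connections and a tanh output.
3. **Losses** (`totalInpaintLoss` and friends). Least-squares adversarial
   terms from a global discriminator (whole images) and a local
   discriminator (glomeruli white-filled to full crop size,
   `R = X * M + (1 - M)`); global and local L1; perceptual and style (Gram)
   distances from a frozen feature extractor. The total is the weighted sum
   with weights 0.02 (adversarial), 1 (both L1 terms), 0.1 (perceptual) and
   150 (style) — the style weight dominates in magnitude, but Gram distances of near-identical images are tiny.
4. **Mask synthesis** (`trainMaskGAN`, `postprocessMask`,
   `rescaleContours`, `balanceSizeDistribution`). A DCGAN (64x64) learns
   the shape distribution of real sclerosed-glomerulus masks; samples are
   upsampled, thresholded, cleaned of small components, and per-component
   rescaled so mask areas are evenly distributed across size bins.
5. **ROI synthesis** (`proposePositions`, `synthesizeROI`). Candidate
   256x256 windows must lie in tissue and avoid annotated glomeruli; the
   generator inpaints a randomly assigned synthetic mask into each window
   (`Xgap_t = Xori_t * (1 - Xgmask)`), the composite
   `Xrec * M + Xori * (1 - M)` is pasted back, and one sclerosed polygon
   per mask component (traced along pixel edges) is appended to the
   annotations. Pixels outside the masks are bitwise untouched.
6. **Segmentation** (`buildSegModel`, `trainSegmenter`, `predictSlide`).
   A staged convolutional encoder feeds a U-shaped decoder with one skip
   per stage; two independent sigmoid channels (normal, sclerosed) because
   a pixel's class resolution is handled downstream (sclerosed wins ties).
   Training minimizes `0.5 * BCE + Dice` with Adam under cosine annealing
   to a floor of 1e-5 over 200 epochs, 8:2 train/validation, online
   flip/rotate augmentation; the checkpoint with the highest validation
   mean Dice is kept (selecting the lowest would contradict the metric's
   direction). Inference tiles with half
   overlap and averages probabilities in overlaps.
7. **Metrics** (`confusionMetrics`, `imageQuality`). Pixel precision,
   recall, F1 and Dice (`2TP / (FP + 2TP + FN)`), pooled micro-style across
   rasters; MAE, PSNR (peak 1.0) and 11x11 Gaussian-window SSIM
   (sigma 1.5, K1 = 0.01, K2 = 0.03), full-image and masked-region.

## Numerical and design choices

* **Autodiff engine.** All four networks run on a compact reverse-mode
  autodiff engine written for this package (R tape, compiled
  im2col/col2im convolution kernels). It supports exactly the operator set
  the architectures need; gradients of every operator are tested against
  central differences at small sizes.
* **AOT block internals.** Four branches with 3x3 kernels and dilation
  rates {1, 2, 4, 8}; the input is split into four equal channel groups,
  branch outputs are concatenated and fused 1x1; a spatial gate
  `beta = sigmoid(conv3x3(x))` mixes `beta * x + (1 - beta) * x2`. The
  gating orientation is ambiguous in prose, so `gateOnResidual` flips it
  for ablations. With a zero-initialized gate both orientations coincide.
* **Self-attention.** Query/key width `C/8`, learned scalar gain
  initialized to 0, so a fresh block is exactly the identity and the
  network's ablation equals itself at initialization.
* **Discriminators.** Six 4x4 stride-2 convolutions; the five default
  widths (64...512, 1) are extended to six layers by repeating the
  penultimate width. No normalization on the first and last layers
  (standard patch-discriminator practice). The same architecture serves
  globally and locally.
* **Feature extractor for perceptual/style losses.** Pretrained weights
  are deliberately not bundled; the extractor is injected. The default is
  a fixed-seed frozen random convolutional stack — random features still
  define a valid distance, though a weaker one than a pretrained
  backbone — and tests use an identity extractor where exact values
  matter. The Gram matrix is normalized by the feature map's element
  count.
* **Mask post-processing.** Luma conversion, binarization at 0.5,
  8-connected components below 200 px removed (both thresholds
  configurable). Rescaling uses
  nearest-neighbour resampling about each component centroid; factors for
  size balancing move a mask toward the target bin's midpoint area.
* **Tiny-GAN stabilizers.** At desk scale the mask DCGAN mode-collapses
  under plain alternating updates. The training loop therefore uses
  one-sided label smoothing (real target 0.9) and two generator updates
  per discriminator update; with those, sampled foreground fractions land
  within a factor of ~1.6 of the real-mask mean across training seeds.
* **Edge policies.** Tiling shifts the final window flush with the image
  edge (duplicated coverage rather than padding); crops near borders are
  translated inward so the network never sees synthetic padding; rasters
  smaller than one window are reflect-padded.
* **Degenerate inputs.** Polygons with fewer than three distinct vertices
  are skipped with a warning; a pixel claimed by both classes goes to the
  sclerosed mask; 0/0 metric ratios resolve to 0, except the doubly-empty
  comparison which counts as perfect agreement; identical images give a
  PSNR of `Inf` rather than an error; soft Dice uses epsilon 1e-6.

## What the fixtures emulate — and what they do not

`makeFixtureSlide` draws a textured pink field (tissue) with a white
margin (background), "normal" glomeruli as ellipses with dotted
dark-purple interiors and "sclerosed" ones as smooth homogeneous dark
ellipses, plus exact polygon annotations; `makeFixtureCrops` makes centred
crop/mask pairs. The classes are separable by interior variance **by
construction**, which is what lets a tiny segmenter overfit them and a
tiny inpainter reconstruct them quickly. Passing the packaged tests
therefore demonstrates that the machinery is correct — losses, gradients,
geometry, compositing, training dynamics — not that the models reach any
particular quality on real stained tissue, which differs in texture
statistics, stain variation, artefacts and scale.

## Problem sizes used by the packaged checks

The test suite and `scripts/acceptance.R` run everything at reduced scale,
chosen as the smallest sizes at which each property is still meaningful:
64x64 inpainting crops with a width-4 generator (200 optimization steps),
a 64x64 DCGAN with width 16 trained for 100 epochs on 40 masks, 128x128
segmentation tiles with the `"tiny"` U-Net preset (150 epochs on 4 tiles),
and full-geometry (256x256, width-4) forward passes for the architecture
contracts. The full-scale training settings (Adam 1e-4, betas 0.5/0.999,
batch 16, 100 epochs for the inpainter; batch 8, cosine annealing, 200
epochs for the segmenter) are the package defaults.

## Known limitations

* No pyramidal slide decoding; inputs are pre-exported PNG rasters.
* No stain normalization and no colour augmentation beyond flips and
  rotations.
* The CPU engine is single-threaded and desk-scale; reproducing
  full-resolution WSI training is out of scope.
* Generated glomeruli inherit the texture statistics of the training
  crops; the mask GAN controls shape, not sclerosis grade.
* Adjacent-tissue (background) synthesis is intentionally not implemented.
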