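## Loss computations for the inpainting network (adversarial, pixel,
## perceptual, style and their weighted total) and the combined
## cross-entropy + Dice segmentation loss. These operate on plain arrays and
## mirror exactly what the training loop computes on the autodiff tape.

maskTo3 <- function(mask) array(rep(mask, 3), dim = c(dim(mask), 3))

#' Build the inpainting network input from an image and a mask
#'
#' `Xgap = Xori * (1 - Xmask)` blanks the glomerulus; `Xinput` stacks
#' `Xgap` (3 channels) and `Xmask` (1 channel).
#'
#' @param Xori numeric array `c(s, s, 3)` in `[0, 1]`.
#' @param Xmask binary `s x s` matrix (1 = glomerulus).
#' @return An [InpaintSample-class].
#' @export
makeInpaintInput <- function(Xori, Xmask) {
  d <- dim(Xori)
  if (length(d) != 3 || d[3] != 3) stop("Xori must be H x W x 3")
  if (!all(dim(Xmask) == d[1:2])) stop("Xori/Xmask shape mismatch")
  if (!all(Xmask %in% c(0, 1))) stop("Xmask must be binary")
  Xgap <- Xori * maskTo3(1 - Xmask)
  Xinput <- array(c(Xgap, Xmask), dim = c(d[1], d[2], 4))
  new("InpaintSample", Xori = Xori, Xmask = Xmask, Xgap = Xgap,
      Xinput = Xinput)
}

#' White-filled local glomerulus region
#'
#' `R = X * Xmask + (1 - Xmask)`: the glomerulus keeps its pixels and the
#' background is filled white so the local discriminator sees inputs of the
#' full crop size.
#'
#' @param X raster in `[0, 1]` (`H x W` or `H x W x 3`).
#' @param Xmask binary `H x W` matrix.
#' @return Raster of the same shape as `X`.
#' @export
localRegion <- function(X, Xmask) {
  m <- if (length(dim(X)) == 3) maskTo3(Xmask) else Xmask
  X * m + (1 - m)
}

#' Least-squares adversarial losses from patch score maps
#'
#' The discriminator minimizes `E[D(fake)^2] + E[(1 - D(real))^2]`; the
#' generator term is `E[(1 - D(fake))^2]`. Expectations average over all
#' patch scores (and the batch when score maps are stacked).
#'
#' @param Dreal,Dfake score maps of identical shape (real / reconstructed
#'   inputs).
#' @return `list(discriminator, generator)`.
#' @export
adversarialLosses <- function(Dreal, Dfake) {
  if (!all((dim(Dreal) %||% length(Dreal)) == (dim(Dfake) %||% length(Dfake))))
    stop("score map shape mismatch")
  list(discriminator = mean(Dfake^2) + mean((1 - Dreal)^2),
       generator = mean((1 - Dfake)^2))
}

#' Global and local pixel reconstruction losses
#'
#' Mean absolute differences: global over the full images, local over the
#' white-filled glomerulus regions.
#'
#' @param sample an [InpaintSample-class].
#' @param Xrec generator output mapped to `[0, 1]`, same shape as `Xori`.
#' @return `list(l1g, l1l)`.
#' @export
l1Losses <- function(sample, Xrec) {
  stopifnot(is(sample, "InpaintSample"))
  if (!all(dim(Xrec) == dim(sample@Xori))) stop("Xrec shape mismatch")
  Rori <- localRegion(sample@Xori, sample@Xmask)
  Rrec <- localRegion(Xrec, sample@Xmask)
  list(l1g = mean(abs(sample@Xori - Xrec)), l1l = mean(abs(Rori - Rrec)))
}

## ---- feature extractors ---------------------------------------------------

#' Identity feature extractor (test double)
#'
#' A single "layer" returning the image itself, so the perceptual loss
#' reduces to the mean absolute pixel difference. Useful for desk-scale
#' tests of the perceptual/style machinery.
#'
#' @return A feature extractor usable with [perceptualAndStyle()].
#' @export
identityFeatureExtractor <- function() {
  structure(list(layers = "identity",
                 forwardAg = function(x) list(identity = x)),
            class = "glomFeatureExtractor")
}

#' Frozen random convolutional feature extractor
#'
#' A fixed-seed stack of strided 3x3 convolution + ReLU stages standing in
#' for a pretrained perceptual backbone. Weights are random but frozen, so
#' feature distances still define a valid (if weaker) perceptual metric;
#' the extractor is injectable wherever a pretrained network would be used.
#'
#' @param nStages number of conv stages (each halves resolution).
#' @param base channel width of the first stage (doubles per stage).
#' @param seed RNG seed for the frozen weights.
#' @return A feature extractor usable with [perceptualAndStyle()].
#' @export
convFeatureExtractor <- function(nStages = 3L, base = 8L, seed = 1234L) {
  weights <- withSeed(seed, {
    cin <- 3L
    lapply(seq_len(nStages), function(i) {
      cout <- as.integer(base * 2^(i - 1))
      w <- agTensor(mkConvW(cout, cin, 3L) * 5) # wider fan for nonzero relu
      b <- agTensor(numeric(cout))
      cin <<- cout
      list(w = w, b = b)
    })
  })
  forwardAg <- function(x) {
    feats <- list()
    h <- x
    for (i in seq_along(weights)) {
      h <- agLeakyReLU(agConv(h, weights[[i]]$w, weights[[i]]$b,
                              stride = 2L, pad = 1L), slope = 0)
      feats[[paste0("relu", i)]] <- h
    }
    feats
  }
  structure(list(layers = paste0("relu", seq_len(nStages)),
                 forwardAg = forwardAg),
            class = "glomFeatureExtractor")
}

extractFeatures <- function(phi, image) {
  x <- agTensor(array(image, dim = c(dim(image)[1], dim(image)[2],
                                     dim(image)[3], 1)))
  agNoGrad(lapply(phi$forwardAg(x), function(f) {
    d <- dim(f$v)
    array(f$v, dim = d[1:3])
  }))
}

gramMatrix <- function(feat) {
  d <- dim(feat)
  Fm <- matrix(feat, nrow = d[1] * d[2], ncol = d[3])
  crossprod(Fm) / length(feat)
}

#' Perceptual and style losses from a frozen feature extractor
#'
#' `Lper = sum_i mean|phi_i(Xori) - phi_i(Xrec)|` (the L1 norm of each layer
#' difference divided by its element count) and `Lsty` is the mean over
#' layers of the mean absolute difference between Gram matrices
#' `t(F) F / N_i` of the layer features.
#'
#' @param Xori,Xrec rasters `c(s, s, 3)` in `[0, 1]`.
#' @param phi a feature extractor ([identityFeatureExtractor()] or
#'   [convFeatureExtractor()]).
#' @param layers optional subset of layer names.
#' @return `list(per, sty, perLayer)` with per-layer contributions.
#' @export
perceptualAndStyle <- function(Xori, Xrec, phi = identityFeatureExtractor(),
                               layers = NULL) {
  fa <- extractFeatures(phi, Xori)
  fb <- extractFeatures(phi, Xrec)
  if (is.null(layers)) layers <- names(fa)
  missing <- setdiff(layers, names(fa))
  if (length(missing) > 0)
    stop("unknown feature layers: ", paste(missing, collapse = ", "))
  perL <- styL <- setNames(numeric(length(layers)), layers)
  for (nm in layers) {
    A <- if (length(dim(fa[[nm]])) == 2) array(fa[[nm]], c(dim(fa[[nm]]), 1)) else fa[[nm]]
    B <- if (length(dim(fb[[nm]])) == 2) array(fb[[nm]], c(dim(fb[[nm]]), 1)) else fb[[nm]]
    perL[nm] <- mean(abs(A - B))
    styL[nm] <- mean(abs(gramMatrix(A) - gramMatrix(B)))
  }
  list(per = sum(perL), sty = mean(styL),
       perLayer = list(per = perL, sty = styL))
}

#' Default loss weights
#'
#' The default weighting of the composite objective: adversarial 0.02,
#' global and local pixel losses 1, perceptual 0.1, style 150.
#'
#' @return named numeric vector `c(adv, l1g, l1l, per, sty)`.
#' @export
lossWeights <- function() {
  c(adv = 0.02, l1g = 1, l1l = 1, per = 0.1, sty = 150)
}

#' Weighted total inpainting loss
#'
#' `Ltotal = adv*(advg + advl) + l1g*L1g + l1l*L1l + per*Lper + sty*Lsty`.
#'
#' @param advg,advl,l1g,l1l,per,sty nonnegative loss components.
#' @param weights named weights as from [lossWeights()].
#' @return A [LossReport-class].
#' @export
totalInpaintLoss <- function(advg, advl, l1g, l1l, per, sty,
                             weights = lossWeights()) {
  comps <- c(advg, advl, l1g, l1l, per, sty)
  if (any(!is.finite(comps))) stop("non-finite loss component")
  if (any(comps < 0)) stop("negative loss component")
  total <- weights["adv"] * (advg + advl) + weights["l1g"] * l1g +
    weights["l1l"] * l1l + weights["per"] * per + weights["sty"] * sty
  new("LossReport", advg = advg, advl = advl, l1g = l1g, l1l = l1l,
      per = per, sty = sty, total = unname(total), perLayer = list(),
      weights = weights)
}

#' Combined cross-entropy and Dice segmentation loss
#'
#' `Lseg = lambda * LBCE + LDice` with the soft Dice loss
#' `1 - (2*sum(p*t) + eps) / (sum(p) + sum(t) + eps)`.
#'
#' @param pred predicted probabilities in `(0, 1)`.
#' @param target binary target of the same shape.
#' @param lambda cross-entropy weight (default 0.5).
#' @param eps Dice smoothing constant.
#' @return scalar loss.
#' @export
segLoss <- function(pred, target, lambda = 0.5, eps = 1e-6) {
  if (!all((dim(pred) %||% length(pred)) == (dim(target) %||% length(target))))
    stop("pred/target shape mismatch")
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  dice <- 1 - (2 * sum(p * target) + eps) / (sum(p) + sum(target) + eps)
  lambda * bce + dice
}
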