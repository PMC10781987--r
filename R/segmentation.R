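## Encoder-decoder glomerulus segmentation: staged convolutional encoder
## with U-style decoder and skip connections, two independent sigmoid
## output channels (normal, sclerosed), combined BCE + Dice training with
## cosine-annealed Adam, and overlap-averaged tiled inference.

segBackbones <- function() list(
  ## widths per encoder stage (first stage keeps full resolution);
  ## convsPerStage deepens the larger preset
  "tiny" = list(widths = c(8L, 16L, 32L), convsPerStage = 1L),
  "efficientnet-b3-like" = list(widths = c(24L, 32L, 48L, 96L),
                                convsPerStage = 2L))

#' Build a segmentation model
#'
#' Staged strided-convolution encoder feeding a U-shaped decoder; every
#' encoder stage contributes exactly one skip connection to its matching
#' decoder stage. The output is a 2-channel sigmoid map (normal, sclerosed)
#' at input resolution. The `"efficientnet-b3-like"` preset uses staged
#' widths inspired by that backbone family; `"tiny"` is a desk-scale preset
#' for tests and small fixtures.
#'
#' @param backbone registry key; see [segBackbones()] names.
#' @param seed optional RNG seed for the weights.
#' @return segmentation model; run with [segForward()] or [predictSlide()].
#' @export
buildSegModel <- function(backbone = "efficientnet-b3-like", seed = NULL) {
  reg <- segBackbones()
  if (!backbone %in% names(reg))
    stop(sprintf("unknown backbone '%s'; registry: %s", backbone,
                 paste(names(reg), collapse = ", ")))
  spec <- reg[[backbone]]
  widths <- spec$widths
  ns <- length(widths)
  args <- list(backbone = backbone, seed = seed)
  build <- function() {
    m <- mkModule(list(type = "segmenter", args = args))
    enc <- list(); encBN <- list(); enc2 <- list(); enc2BN <- list()
    cin <- 3L
    for (i in seq_len(ns)) {
      enc[[i]] <- addConv(m, sprintf("enc%d", i), cin, widths[i], 3L,
                          stride = if (i == 1) 1L else 2L, pad = 1L)
      encBN[[i]] <- addBN(m, sprintf("enc%d.bn", i), widths[i])
      if (spec$convsPerStage > 1) {
        enc2[[i]] <- addConv(m, sprintf("enc%db", i), widths[i], widths[i],
                             3L, pad = 1L)
        enc2BN[[i]] <- addBN(m, sprintf("enc%db.bn", i), widths[i])
      }
      cin <- widths[i]
    }
    dec <- list(); decBN <- list(); fuse <- list(); fuseBN <- list()
    for (i in seq_len(ns - 1L)) {
      ## decoder stage i upsamples widths[ns-i+1] -> widths[ns-i]
      chOut <- widths[ns - i]
      dec[[i]] <- addConvT(m, sprintf("dec%d", i), widths[ns - i + 1L], chOut)
      decBN[[i]] <- addBN(m, sprintf("dec%d.bn", i), chOut)
      fuse[[i]] <- addConv(m, sprintf("fuse%d", i), 2L * chOut, chOut, 3L,
                           pad = 1L)
      fuseBN[[i]] <- addBN(m, sprintf("fuse%d.bn", i), chOut)
    }
    outc <- addConv(m, "out", widths[1], 2L, 1L)
    m$forward <- function(x, training = TRUE) {
      skips <- list()
      h <- x
      for (i in seq_len(ns)) {
        h <- agLeakyReLU(encBN[[i]](enc[[i]](h), training))
        if (spec$convsPerStage > 1)
          h <- agLeakyReLU(enc2BN[[i]](enc2[[i]](h), training))
        skips[[i]] <- h
      }
      for (i in seq_len(ns - 1L)) {
        h <- agLeakyReLU(decBN[[i]](dec[[i]](h), training))
        h <- agConcatC(h, skips[[ns - i]])
        h <- agLeakyReLU(fuseBN[[i]](fuse[[i]](h), training))
      }
      outc(h) # logits; apply sigmoid at the surface
    }
    m
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Forward pass of a segmentation model
#'
#' @param model from [buildSegModel()].
#' @param image numeric array `c(H, W, 3)` (H, W divisible by
#'   `2^(stages-1)`).
#' @param training use batch (TRUE) or running (FALSE) normalization
#'   statistics.
#' @return probability array `c(H, W, 2)` in `(0, 1)`: channel 1 normal,
#'   channel 2 sclerosed.
#' @export
segForward <- function(model, image, training = FALSE) {
  d <- dim(image)
  x <- array(image, dim = c(d[1], d[2], 3, 1))
  logits <- agNoGrad(model$forward(agTensor(x), training = training))$v
  array(1 / (1 + exp(-logits)), dim = c(d[1], d[2], 2))
}

#' Segmentation training configuration
#'
#' Published settings: batch 8, Adam, cosine-annealed learning rate with
#' minimum 1e-5, 200 epochs, 8:2 train/validation split, loss weight
#' lambda = 0.5. The initial learning rate defaults to 1e-3.
#'
#' @param batchSize minibatch size.
#' @param lr initial learning rate.
#' @param lrMin cosine-annealing floor.
#' @param epochs training epochs.
#' @param split training fraction (1 disables validation).
#' @param lambda BCE weight in the combined loss.
#' @param tradAug logical; apply online flip/rotate augmentation.
#' @param pFlip,pRot per-sample flip / 90-degree-rotation probabilities.
#' @param seed RNG seed.
#' @return config list.
#' @export
segTrainConfig <- function(batchSize = 8L, lr = 1e-3, lrMin = 1e-5,
                           epochs = 200L, split = 0.8, lambda = 0.5,
                           tradAug = TRUE, pFlip = 0.5, pRot = 0.5,
                           seed = 1L) {
  list(batchSize = as.integer(batchSize), lr = lr, lrMin = lrMin,
       epochs = as.integer(epochs), split = split, lambda = lambda,
       tradAug = tradAug, pFlip = pFlip, pRot = pRot,
       seed = as.integer(seed))
}

rot90a <- function(x, k = 1L) {
  k <- k %% 4L
  if (k == 0) return(x)
  ## one 90-degree turn maps pixel (x, y) to (y, W-1-x)
  f <- function(mat) t(mat[, ncol(mat):1, drop = FALSE])
  g <- function(mat) { for (i in seq_len(k)) mat <- f(mat); mat }
  if (is.matrix(x)) return(g(x))
  d <- dim(x)
  out <- NULL
  for (c in seq_len(d[3])) {
    r <- g(x[, , c])
    if (is.null(out)) out <- array(0, dim = c(dim(r), d[3]))
    out[, , c] <- r
  }
  out
}

flipH <- function(x) if (is.matrix(x)) x[, ncol(x):1, drop = FALSE] else
  x[, dim(x)[2]:1, , drop = FALSE]
flipV <- function(x) if (is.matrix(x)) x[nrow(x):1, , drop = FALSE] else
  x[dim(x)[1]:1, , , drop = FALSE]

#' Traditional (flip/rotate) augmentation of a segmentation sample
#'
#' Applies horizontal/vertical flips (each with probability `pFlip`) and a
#' random multiple-of-90-degree rotation (with probability `pRot`),
#' identically to the image and its target masks.
#'
#' @param sample `list(image = c(H, W, 3) array, target = c(H, W, 2)
#'   array)`.
#' @param pFlip,pRot probabilities in `[0, 1]`.
#' @param seed optional seed for reproducible augmentation.
#' @return augmented sample of the same structure.
#' @export
traditionalAugment <- function(sample, pFlip = 0.5, pRot = 0.5, seed = NULL) {
  stopifnot(pFlip >= 0, pFlip <= 1, pRot >= 0, pRot <= 1)
  doIt <- function() {
    img <- sample$image; tgt <- sample$target
    if (stats::runif(1) < pFlip) { img <- flipH(img); tgt <- flipH(tgt) }
    if (stats::runif(1) < pFlip) { img <- flipV(img); tgt <- flipV(tgt) }
    if (stats::runif(1) < pRot) {
      k <- sample.int(3L, 1L)
      img <- rot90a(img, k); tgt <- rot90a(tgt, k)
    }
    list(image = img, target = tgt)
  }
  if (is.null(seed)) doIt() else withSeed(seed, doIt())
}

#' Convert a Tile into a segmentation training sample
#' @param tile a [Tile-class].
#' @return `list(image, target)` with a 2-channel target (normal,
#'   sclerosed).
#' @export
tileToSegSample <- function(tile) {
  d <- dim(tile@image)
  list(image = tile@image,
       target = array(c(tile@maskNormal, tile@maskSclerosed),
                      dim = c(d[1], d[2], 2)))
}

segBatchLoss <- function(model, images, targets, lambda, training = TRUE) {
  logits <- model$forward(agTensor(images), training = training)
  p <- agSigmoid(logits)
  t <- targets
  bce <- agMeanAll(agSub(agSoftplus(logits), agMulC(logits, t)))
  eps <- 1e-6
  diceLosses <- lapply(1:2, function(ch) {
    pc <- agSliceC(p, ch, ch)
    tc <- t[, , ch, , drop = FALSE]
    num <- agAddC(agMulC(agSumAll(agMulC(pc, tc)), 2), eps)
    den <- agAddC(agSumAll(pc), sum(tc) + eps)
    agRsubC(1, agDivSc(num, den))
  })
  dice <- agMulC(Reduce(agAdd, diceLosses), 0.5)
  list(loss = agAdd(agMulC(bce, lambda), dice), p = p, bce = bce,
       dice = dice)
}

segDicePerClass <- function(model, samples) {
  reps <- list(normal = list(), sclerosed = list())
  for (s in samples) {
    pr <- segForward(model, s$image, training = FALSE)
    hard <- resolveClassProbs(pr)
    reps$normal[[length(reps$normal) + 1L]] <-
      confusionMetrics(hard[, , 1], s$target[, , 1])
    reps$sclerosed[[length(reps$sclerosed) + 1L]] <-
      confusionMetrics(hard[, , 2], s$target[, , 2])
  }
  c(normal = aggregateConfusion(reps$normal)$dice,
    sclerosed = aggregateConfusion(reps$sclerosed)$dice)
}

## threshold at 0.5 with per-pixel exclusivity; sclerosed wins ties
resolveClassProbs <- function(probs) {
  pn <- probs[, , 1] > 0.5
  ps <- probs[, , 2] > 0.5
  both <- pn & ps
  pn[both] <- probs[, , 1][both] > probs[, , 2][both]
  ps[both] <- !pn[both]
  array(c(pn * 1, ps * 1), dim = dim(probs))
}

#' Train the glomerulus segmentation model
#'
#' Minimizes `lambda * BCE + Dice` with Adam under a cosine-annealed
#' learning rate, with optional online flip/rotate augmentation, logs
#' per-epoch training loss and per-class validation Dice, and keeps both
#' the final model and the weights with the highest validation mean Dice.
#'
#' @param samples list of `list(image, target)` segmentation samples (see
#'   [tileToSegSample()] for converting [Tile-class] objects).
#' @param config a [segTrainConfig()].
#' @param model optional prebuilt model (default: tiny preset is NOT
#'   assumed; pass `backbone` instead).
#' @param backbone registry key used when `model` is NULL.
#' @return `list(model, bestValues, log)`; `bestValues` are the
#'   best-validation weights (load with `moduleLoadValues`), `log` a
#'   per-epoch data frame.
#' @export
trainSegmenter <- function(samples, config = segTrainConfig(), model = NULL,
                           backbone = "tiny") {
  if (length(samples) == 0) stop("empty training manifest")
  withSeed(config$seed, {
    if (is.null(model)) model <- buildSegModel(backbone)
    n <- length(samples)
    ntr <- max(1L, round(config$split * n))
    ord <- sample.int(n)
    trIdx <- ord[seq_len(ntr)]
    vaIdx <- setdiff(ord, trIdx)
    opt <- adamInit(model$params)
    logRows <- list()
    best <- list(dice = -Inf, values = NULL, epoch = 0L)
    for (ep in seq_len(config$epochs)) {
      lr <- cosineLR(ep - 1L, config$epochs, config$lr, config$lrMin)
      ordEp <- sample(trIdx)
      bs <- min(config$batchSize, length(ordEp))
      nb <- max(1L, length(ordEp) %/% bs)
      epLoss <- 0
      for (b in seq_len(nb)) {
        idx <- ordEp[((b - 1L) * bs + 1L):min(b * bs, length(ordEp))]
        batchSamples <- lapply(samples[idx], function(s)
          if (config$tradAug)
            traditionalAugment(s, config$pFlip, config$pRot) else s)
        d <- dim(batchSamples[[1]]$image)
        N <- length(batchSamples)
        images <- array(0, dim = c(d[1], d[2], 3, N))
        targets <- array(0, dim = c(d[1], d[2], 2, N))
        for (i in seq_len(N)) {
          images[, , , i] <- batchSamples[[i]]$image
          targets[, , , i] <- batchSamples[[i]]$target
        }
        agZeroGrad(model$params)
        L <- segBatchLoss(model, images, targets, config$lambda,
                          training = TRUE)
        if (!is.finite(L$loss$v))
          stop(sprintf("non-finite segmentation loss at epoch %d batch %d",
                       ep, b))
        agBackward(L$loss)
        adamStep(model$params, opt, lr, 0.9, 0.999)
        epLoss <- epLoss + as.numeric(L$loss$v) / nb
      }
      valDice <- if (length(vaIdx) > 0)
        segDicePerClass(model, samples[vaIdx]) else c(normal = NA_real_,
                                                      sclerosed = NA_real_)
      meanDice <- mean(valDice)
      if (!is.na(meanDice) && meanDice > best$dice) {
        best <- list(dice = meanDice, values = moduleValues(model),
                     epoch = ep)
      }
      logRows[[ep]] <- data.frame(epoch = ep, lr = lr, train_loss = epLoss,
                                  val_dice_normal = valDice[["normal"]],
                                  val_dice_sclerosed = valDice[["sclerosed"]])
    }
    if (is.null(best$values)) best$values <- moduleValues(model)
    list(model = model, bestValues = best$values, bestEpoch = best$epoch,
         log = do.call(rbind, logRows))
  })
}

#' Tiled whole-slide prediction
#'
#' Tiles the raster with a window equal to the model's expected input and
#' half-window stride, averages probabilities where tiles overlap,
#' thresholds at 0.5 and resolves per-pixel class conflicts in favour of
#' the sclerosed class. Rasters smaller than the window are reflect-padded
#' and cropped back.
#'
#' @param model trained segmentation model.
#' @param image numeric array `c(H, W, 3)`.
#' @param window tile size (default 1024).
#' @param stride tile stride (default `window / 2`).
#' @return `list(maskNormal, maskSclerosed, probs)`; masks are 0/1
#'   matrices, `probs` the averaged `c(H, W, 2)` probability array.
#' @export
predictSlide <- function(model, image, window = 1024L, stride = NULL) {
  window <- as.integer(window)
  if (is.null(stride)) stride <- window %/% 2L
  d0 <- dim(image)
  padded <- d0[1] < window || d0[2] < window
  if (padded) image <- reflectPadTo(image, max(d0[1], window),
                                    max(d0[2], window))
  d <- dim(image)
  acc <- array(0, dim = c(d[1], d[2], 2))
  cnt <- matrix(0, d[1], d[2])
  for (y0 in axisStarts(d[1], window, stride)) {
    for (x0 in axisStarts(d[2], window, stride)) {
      ry <- (y0 + 1L):(y0 + window); rx <- (x0 + 1L):(x0 + window)
      pr <- segForward(model, image[ry, rx, , drop = FALSE],
                       training = FALSE)
      acc[ry, rx, ] <- acc[ry, rx, ] + pr
      cnt[ry, rx] <- cnt[ry, rx] + 1
    }
  }
  probs <- acc / array(cnt, dim = dim(acc))
  if (padded) probs <- probs[seq_len(d0[1]), seq_len(d0[2]), , drop = FALSE]
  hard <- resolveClassProbs(probs)
  list(maskNormal = hard[, , 1], maskSclerosed = hard[, , 2], probs = probs)
}
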