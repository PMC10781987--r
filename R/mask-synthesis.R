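## DCGAN-based synthesis of novel sclerosed-glomerulus masks and their
## post-processing: grayscale + threshold binarization, small-region
## removal, and per-component contour rescaling for size balancing.
##
## The GAN operates at a low resolution (64x64 by default; masks are
## low-frequency shapes) and samples are bilinearly upsampled to the working
## resolution before thresholding re-binarizes them.

#' DCGAN configuration for mask synthesis
#'
#' @param latentDim latent vector length.
#' @param imageSize GAN working resolution (power of two).
#' @param baseWidth channel width scale of generator/discriminator.
#' @param lr Adam learning rate.
#' @param batchSize minibatch size.
#' @param epochs training epochs over the real-mask set.
#' @param labelSmooth one-sided label-smoothing target for real samples
#'   (standard DCGAN stabilizer; 1 disables it).
#' @param gSteps generator updates per discriminator update (keeping the
#'   generator competitive at small scale).
#' @param seed RNG seed for weights and sampling order.
#' @return config list.
#' @export
maskGANConfig <- function(latentDim = 64L, imageSize = 64L, baseWidth = 16L,
                          lr = 2e-4, batchSize = 16L, epochs = 100L,
                          labelSmooth = 0.9, gSteps = 2L, seed = 1L) {
  if (bitwAnd(imageSize, imageSize - 1L) != 0L)
    stop("imageSize must be a power of two")
  list(latentDim = as.integer(latentDim), imageSize = as.integer(imageSize),
       baseWidth = as.integer(baseWidth), lr = lr,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       labelSmooth = labelSmooth, gSteps = as.integer(gSteps),
       seed = as.integer(seed))
}

#' Build the DCGAN mask generator
#'
#' Latent vector -> dense projection to a 4x4 map -> four transposed
#' convolutions (batch norm + ReLU) -> sigmoid single-channel raster in
#' `[0, 1]`.
#'
#' @param latentDim latent size.
#' @param imageSize output resolution (64 supported by the 4-stage stack).
#' @param baseWidth width scale.
#' @param seed optional RNG seed.
#' @return generator model with `$forward(z, training)`.
#' @export
buildMaskGenerator <- function(latentDim = 64L, imageSize = 64L,
                               baseWidth = 32L, seed = NULL) {
  stopifnot(imageSize == 64L)
  w <- as.integer(baseWidth)
  args <- list(latentDim = latentDim, imageSize = imageSize,
               baseWidth = baseWidth, seed = seed)
  if (is.null(seed)) build0(args, w, latentDim)
  else withSeed(seed, build0(args, w, latentDim))
}

## builder kept separate so trainMaskGAN can construct under its own seed
build0 <- function(args, w, latentDim) {
  m <- mkModule(list(type = "mask_generator", args = args))
  fc <- regParam(m, "fc.w", matrix(stats::rnorm(latentDim * 16 * 4 * w,
                                                0, 0.02), nrow = latentDim))
  fcb <- regParam(m, "fc.b", numeric(16L * 4L * w))
  bn0 <- addBN(m, "bn0", 4L * w)
  up1 <- addConvT(m, "up1", 4L * w, 2L * w); bn1 <- addBN(m, "bn1", 2L * w)
  up2 <- addConvT(m, "up2", 2L * w, w); bn2 <- addBN(m, "bn2", w)
  up3 <- addConvT(m, "up3", w, max(w %/% 2L, 4L))
  bn3 <- addBN(m, "bn3", max(w %/% 2L, 4L))
  up4 <- addConvT(m, "up4", max(w %/% 2L, 4L), 1L)
  m$forward <- function(z, training = TRUE) {
    ## z: (N x latentDim) matrix tensor -> (64,64,1,N)
    proj <- agAdd(agMatmul(z, fc),
                  agNode(matrix(fcb$v, nrow = nrow(z$v), ncol = length(fcb$v),
                                byrow = TRUE), list(fcb), function(g)
                                  list(colSums(g))))
    h <- agMat2Feat(proj, 4L, 4L, 4L * w)
    h <- agLeakyReLU(bn0(h, training), 0)      # ReLU
    h <- agLeakyReLU(bn1(up1(h), training), 0)
    h <- agLeakyReLU(bn2(up2(h), training), 0)
    h <- agLeakyReLU(bn3(up3(h), training), 0)
    agSigmoid(up4(h))
  }
  m
}

## (N x H*W*C) matrix -> (H,W,C,N) feature array
agMat2Feat <- function(a, H, W, C) {
  N <- nrow(a$v)
  v <- array(t(a$v), dim = c(H, W, C, N))
  agNode(v, list(a), function(g)
    list(t(matrix(g, nrow = H * W * C, ncol = N))))
}

#' Build the DCGAN mask discriminator
#'
#' Four 4x4 stride-2 convolutions (LeakyReLU 0.2, batch norm on the middle
#' layers) and a final 4x4 valid convolution to a single realness logit.
#'
#' @param imageSize input resolution (64).
#' @param baseWidth width scale.
#' @param seed optional RNG seed.
#' @return discriminator model with `$forward(x, training)`.
#' @export
buildMaskDiscriminator <- function(imageSize = 64L, baseWidth = 32L,
                                   seed = NULL) {
  stopifnot(imageSize == 64L)
  w <- as.integer(baseWidth)
  args <- list(imageSize = imageSize, baseWidth = baseWidth, seed = seed)
  build <- function() {
    m <- mkModule(list(type = "mask_discriminator", args = args))
    c1 <- addConv(m, "c1", 1L, w %/% 2L, 4L, stride = 2L, pad = 1L)
    c2 <- addConv(m, "c2", w %/% 2L, w, 4L, stride = 2L, pad = 1L)
    b2 <- addBN(m, "b2", w)
    c3 <- addConv(m, "c3", w, 2L * w, 4L, stride = 2L, pad = 1L)
    b3 <- addBN(m, "b3", 2L * w)
    c4 <- addConv(m, "c4", 2L * w, 4L * w, 4L, stride = 2L, pad = 1L)
    b4 <- addBN(m, "b4", 4L * w)
    c5 <- addConv(m, "c5", 4L * w, 1L, 4L) # 4x4 valid -> 1x1 logit
    m$forward <- function(x, training = TRUE) {
      h <- agLeakyReLU(c1(x), 0.2)
      h <- b2(agLeakyReLU(c2(h), 0.2), training)
      h <- b3(agLeakyReLU(c3(h), 0.2), training)
      h <- b4(agLeakyReLU(c4(h), 0.2), training)
      c5(h)
    }
    m
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Train the mask-synthesis DCGAN
#'
#' Standard non-saturating DCGAN objective: the discriminator minimizes
#' binary cross-entropy on real/generated masks, the generator maximizes
#' the discriminator's realness score of its samples. Real masks are
#' resized (nearest neighbour) to the GAN resolution.
#'
#' @param realMasks list of binary `H x W` matrices (>= 2 * batch size).
#' @param config a [maskGANConfig()].
#' @return `list(generator, discriminator, log)`; sample from the generator
#'   with [sampleMasks()].
#' @export
trainMaskGAN <- function(realMasks, config = maskGANConfig()) {
  if (length(realMasks) == 0) stop("empty training set")
  if (length(realMasks) < 2L * config$batchSize)
    stop("need at least 2 * batchSize real masks")
  s <- config$imageSize
  real <- lapply(realMasks, function(mk) cpp_resize_nearest(mk, s, s))
  withSeed(config$seed, {
    gen <- build0(list(latentDim = config$latentDim, imageSize = s,
                       baseWidth = config$baseWidth, seed = config$seed),
                  config$baseWidth, config$latentDim)
    disc <- buildMaskDiscriminator(s, config$baseWidth)
    optG <- adamInit(gen$params)
    optD <- adamInit(disc$params)
    n <- length(real)
    log <- list()
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      nb <- n %/% config$batchSize
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * config$batchSize + 1L):(b * config$batchSize)]
        N <- length(idx)
        xr <- array(0, dim = c(s, s, 1, N))
        for (i in seq_len(N)) xr[, , 1, i] <- real[[idx[i]]]
        z <- matrix(stats::rnorm(N * config$latentDim), nrow = N)
        ## D step (one-sided label smoothing on the real term)
        xf <- agNoGrad(gen$forward(agTensor(z), training = TRUE))$v
        agZeroGrad(disc$params)
        dr <- disc$forward(agTensor(xr), training = TRUE)
        df <- disc$forward(agTensor(xf), training = TRUE)
        sm <- config$labelSmooth
        realTerm <- agAdd(
          agMulC(agMeanAll(agSoftplus(agMulC(dr, -1))), sm),
          agMulC(agMeanAll(agSoftplus(dr)), 1 - sm))
        dloss <- agAdd(realTerm, agMeanAll(agSoftplus(df)))
        agBackward(dloss)
        adamStep(disc$params, optD, config$lr)
        ## G step(s)
        gloss <- NULL
        for (gs in seq_len(config$gSteps)) {
          zg <- if (gs == 1) z else
            matrix(stats::rnorm(N * config$latentDim), nrow = N)
          agZeroGrad(gen$params); agZeroGrad(disc$params)
          fake <- gen$forward(agTensor(zg), training = TRUE)
          gf <- disc$forward(fake, training = TRUE)
          gloss <- agMeanAll(agSoftplus(agMulC(gf, -1)))
          agBackward(gloss)
          adamStep(gen$params, optG, config$lr)
        }
        step <- step + 1L
        log[[step]] <- data.frame(epoch = ep, step = step,
                                  d_loss = as.numeric(dloss$v),
                                  g_loss = as.numeric(gloss$v))
        if (!is.finite(dloss$v) || !is.finite(gloss$v))
          stop(sprintf("non-finite GAN loss at step %d", step))
      }
    }
    list(generator = gen, discriminator = disc,
         log = do.call(rbind, log))
  })
}

#' Sample raw masks from a trained mask generator
#'
#' @param generator from [trainMaskGAN()] / [buildMaskGenerator()].
#' @param n number of samples.
#' @param seed RNG seed for the latents.
#' @param outSize output resolution (bilinear upsample; default 256).
#' @return list of numeric matrices in `[0, 1]` (threshold with
#'   [postprocessMask()]).
#' @export
sampleMasks <- function(generator, n, seed = 1L, outSize = 256L) {
  cfg <- generator$config$args
  withSeed(seed, {
    z <- matrix(stats::rnorm(n * cfg$latentDim), nrow = n)
    out <- agNoGrad(generator$forward(agTensor(z), training = FALSE))$v
    lapply(seq_len(n), function(i) {
      raw <- matrix(out[, , 1, i], nrow = cfg$imageSize)
      if (outSize != cfg$imageSize)
        cpp_resize_bilinear(array(raw, dim = c(dim(raw), 1)),
                            outSize, outSize)[, , 1]
      else raw
    })
  })
}

luma <- function(x) {
  if (length(dim(x)) == 3)
    0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  else x
}

#' Post-process a raw generated mask
#'
#' Grayscale (luma) conversion for colour inputs, binarization at
#' `threshold`, and removal of 8-connected foreground components smaller
#' than `minArea` pixels.
#'
#' @param raw real-valued raster (`H x W` or `H x W x 3`), finite values.
#' @param minArea minimum surviving component area in pixels (default 200).
#' @param threshold binarization threshold on `[0, 1]` luma (default 0.5).
#' @return A [MaskArtifact-class] with provenance `"postprocessed"`.
#' @export
postprocessMask <- function(raw, minArea = 200L, threshold = 0.5) {
  if (any(!is.finite(raw))) stop("raw mask contains non-finite values")
  g <- luma(raw)
  bin <- (g > threshold) * 1L
  storage.mode(bin) <- "integer"
  lab <- cpp_label_components(bin, 8L)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < minArea)
    if (length(drop) > 0) bin[lab %in% drop] <- 0L
  }
  out <- bin * 1.0
  storage.mode(out) <- "double"
  MaskArtifact(out, provenance = "postprocessed")
}

#' Rescale each mask contour about its own centroid
#'
#' Every 8-connected foreground component is scaled by `factor` about its
#' centroid (nearest-neighbour resampling of the binary raster). Components
#' pushed past the raster bounds are clipped with a warning.
#'
#' @param mask a [MaskArtifact-class].
#' @param factor positive scale factor.
#' @return A [MaskArtifact-class] with provenance `"scaled"` and an updated
#'   cumulative `scaleFactor`.
#' @export
rescaleContours <- function(mask, factor) {
  stopifnot(is(mask, "MaskArtifact"))
  if (factor <= 0) stop("factor must be positive")
  r <- mask@raster
  if (factor == 1) return(mask)
  H <- nrow(r); W <- ncol(r)
  bin <- r > 0.5
  storage.mode(bin) <- "integer"
  lab <- cpp_label_components(bin, 8L)
  out <- matrix(0, H, W)
  clipped <- FALSE
  for (cc in seq_len(max(lab, 0))) {
    sel <- lab == cc
    ys <- row(lab)[sel]; xs <- col(lab)[sel]
    cy <- mean(ys); cx <- mean(xs)
    y0 <- min(ys); y1 <- max(ys); x0 <- min(xs); x1 <- max(xs)
    sub <- matrix(0, y1 - y0 + 1L, x1 - x0 + 1L)
    sub[cbind(ys - y0 + 1L, xs - x0 + 1L)] <- 1
    h2 <- max(1L, round(nrow(sub) * factor))
    w2 <- max(1L, round(ncol(sub) * factor))
    sc <- cpp_resize_nearest(sub, h2, w2)
    ## paste so the centroid stays fixed
    oy <- round(cy - (cy - y0 + 0.5) * factor + 0.5)
    ox <- round(cx - (cx - x0 + 0.5) * factor + 0.5)
    ty <- oy:(oy + h2 - 1L); tx <- ox:(ox + w2 - 1L)
    keepy <- ty >= 1 & ty <= H; keepx <- tx >= 1 & tx <= W
    if (!all(keepy) || !all(keepx)) clipped <- TRUE
    out[ty[keepy], tx[keepx]] <- pmax(out[ty[keepy], tx[keepx]],
                                      sc[keepy, keepx, drop = FALSE])
    }
  if (clipped) warning("scaled component clipped at raster bounds")
  MaskArtifact(out, provenance = "scaled",
               scaleFactor = mask@scaleFactor * factor)
}

maskArea <- function(m) sum(maskRaster(m))

#' Balance mask areas across size bins
#'
#' Rescales masks (via [rescaleContours()]) so that each area bin holds an
#' equal share of the set (within one). Bins are `c(lo, hi)` pixel-area
#' ranges; a surplus mask moved to a deficit bin is rescaled towards the
#' bin's midpoint area.
#'
#' @param masks nonempty list of [MaskArtifact-class] objects.
#' @param bins nonempty list of `c(lo, hi)` area ranges (pixels).
#' @param seed RNG seed controlling which masks move.
#' @return list of [MaskArtifact-class] objects, same length as `masks`.
#' @export
balanceSizeDistribution <- function(masks, bins, seed = 1L) {
  if (length(masks) == 0) stop("empty mask list")
  if (length(bins) == 0) stop("empty bin list")
  k <- length(bins)
  n <- length(masks)
  binOf <- function(area) {
    for (i in seq_len(k)) if (area >= bins[[i]][1] && area <= bins[[i]][2])
      return(i)
    NA_integer_
  }
  withSeed(seed, {
    assign <- vapply(vapply(masks, maskArea, numeric(1)), binOf, integer(1))
    ## masks outside every bin join the nearest bin for accounting
    if (any(is.na(assign))) {
      mids <- vapply(bins, mean, numeric(1))
      for (i in which(is.na(assign)))
        assign[i] <- which.min(abs(mids - maskArea(masks[[i]])))
    }
    target <- rep(n %/% k, k)
    if (n %% k > 0) target[seq_len(n %% k)] <- target[seq_len(n %% k)] + 1L
    counts <- tabulate(assign, nbins = k)
    while (any(counts > target) && any(counts < target)) {
      from <- which(counts > target)[1]
      to <- which(counts < target)[1]
      cand <- which(assign == from)
      pick <- cand[sample.int(length(cand), 1L)]
      area <- maskArea(masks[[pick]])
      mid <- mean(bins[[to]])
      f <- sqrt(mid / max(area, 1))
      moved <- rescaleContours(masks[[pick]], f)
      if (maskArea(moved) < bins[[to]][1] || maskArea(moved) > bins[[to]][2]) {
        ## retry against the achieved area once; then declare unreachable
        f2 <- f * sqrt(mid / max(maskArea(moved), 1))
        moved <- rescaleContours(masks[[pick]], f2)
      }
      a2 <- maskArea(moved)
      if (a2 < bins[[to]][1] || a2 > bins[[to]][2])
        stop(sprintf("bin [%g, %g] unreachable at this raster size",
                     bins[[to]][1], bins[[to]][2]))
      masks[[pick]] <- moved
      assign[pick] <- to
      counts <- tabulate(assign, nbins = k)
    }
    masks
  })
}
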