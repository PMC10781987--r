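## Adversarial training of the inpainting network: alternating
## discriminator and generator steps with the composite attention loss,
## plus test-set evaluation.

#' Split crops into training and test sets
#'
#' Reproducible shuffle under `seed`; the training set receives
#' `round(ratio * n)` crops and the test set the remainder.
#'
#' @param crops list (>= 2 elements).
#' @param ratio training fraction (default 0.8, the standard 8:2 split).
#' @param seed RNG seed.
#' @return `list(train, test)` of disjoint sublists.
#' @export
splitDataset <- function(crops, ratio = 0.8, seed = 1L) {
  n <- length(crops)
  if (n < 2) stop("need at least 2 crops to split")
  withSeed(seed, {
    ord <- sample.int(n)
    ntr <- round(ratio * n)
    list(train = crops[ord[seq_len(ntr)]],
         test = crops[ord[setdiff(seq_len(n), seq_len(ntr))]])
  })
}

#' Inpainter training configuration
#'
#' Defaults: Adam with learning rate 1e-4 and
#' betas (0.5, 0.999), batch size 16, 100 epochs.
#'
#' @param lr learning rate.
#' @param beta1,beta2 Adam moment decays.
#' @param batchSize minibatch size.
#' @param epochs training epochs.
#' @param seed RNG seed (weights, shuffling).
#' @param logPath optional JSON-lines file receiving one loss record per
#'   step.
#' @param checkpointDir optional directory for per-epoch checkpoints.
#' @return config list.
#' @export
inpaintTrainConfig <- function(lr = 1e-4, beta1 = 0.5, beta2 = 0.999,
                               batchSize = 16L, epochs = 100L, seed = 1L,
                               logPath = NULL, checkpointDir = NULL) {
  list(lr = lr, beta1 = beta1, beta2 = beta2,
       batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       seed = as.integer(seed), logPath = logPath,
       checkpointDir = checkpointDir)
}

cropsToBatch <- function(crops, idx) {
  s <- nrow(crops[[1]]@mask)
  N <- length(idx)
  Xori <- array(0, dim = c(s, s, 3, N))
  M <- array(0, dim = c(s, s, 1, N))
  for (i in seq_len(N)) {
    Xori[, , , i] <- crops[[idx[i]]]@image
    M[, , 1, i] <- crops[[idx[i]]]@mask
  }
  m3 <- array(0, dim = c(s, s, 3, N))
  for (c in 1:3) m3[, , c, ] <- M[, , 1, ]
  Xinput <- array(0, dim = c(s, s, 4, N))
  Xinput[, , 1:3, ] <- Xori * (1 - m3)
  Xinput[, , 4, ] <- M[, , 1, ]
  list(Xori = Xori, M = M, m3 = m3, Xinput = Xinput)
}

## composite losses on the tape for one batch; returns loss tensors
inpaintLossesAg <- function(gen, batch, weights, phi, training = TRUE,
                            discG = NULL, discL = NULL) {
  out <- gen$forward(agTensor(batch$Xinput), training = training)
  Xrec <- agMulC(agAddC(out, 1), 0.5)                 # [0, 1]
  diff <- agSub(Xrec, agTensor(batch$Xori))
  l1g <- agMeanAll(agAbs(diff))
  Rdiff <- agMulC(diff, batch$m3)                     # Rori - Rrec collapses
  l1l <- agMeanAll(agAbs(Rdiff))
  per <- agTensor(0); sty <- agTensor(0)
  if (!is.null(phi) && (weights["per"] > 0 || weights["sty"] > 0)) {
    fA <- phi$forwardAg(agTensor(batch$Xori))
    fB <- phi$forwardAg(Xrec)
    perTerms <- list(); styTerms <- list()
    for (nm in names(fA)) {
      perTerms[[nm]] <- agMeanAll(agAbs(agSub(fA[[nm]], fB[[nm]])))
      d <- dim(fA[[nm]]$v)
      ## Gram distance per sample, averaged
      gs <- list()
      for (n in seq_len(d[4])) {
        Am <- agToMat(agSelectSample(fA[[nm]], n))
        Bm <- agToMat(agSelectSample(fB[[nm]], n))
        nel <- d[1] * d[2] * d[3]
        Ga <- agMulC(agMatmulTA(Am, Am), 1 / nel)
        Gb <- agMulC(agMatmulTA(Bm, Bm), 1 / nel)
        gs[[n]] <- agMeanAll(agAbs(agSub(Ga, Gb)))
      }
      styTerms[[nm]] <- agMulC(Reduce(agAdd, gs), 1 / d[4])
    }
    per <- Reduce(agAdd, perTerms)
    sty <- agMulC(Reduce(agAdd, styTerms), 1 / length(styTerms))
  }
  advg <- agTensor(0); advl <- agTensor(0)
  if (!is.null(discG)) {
    Rrec <- agAddC(agMulC(Xrec, batch$m3), 1 - batch$m3)
    sg <- discG$forward(Xrec, training = training)
    sl <- discL$forward(Rrec, training = training)
    advg <- agMeanAll(agSqr(agRsubC(1, sg)))
    advl <- agMeanAll(agSqr(agRsubC(1, sl)))
  }
  total <- Reduce(agAdd, list(
    agMulC(agAdd(advg, advl), weights[["adv"]]),
    agMulC(l1g, weights[["l1g"]]),
    agMulC(l1l, weights[["l1l"]]),
    agMulC(per, weights[["per"]]),
    agMulC(sty, weights[["sty"]])))
  list(total = total, Xrec = Xrec, advg = advg, advl = advl, l1g = l1g,
       l1l = l1l, per = per, sty = sty)
}

lossReportFrom <- function(L, weights) {
  new("LossReport", advg = as.numeric(L$advg$v), advl = as.numeric(L$advl$v),
      l1g = as.numeric(L$l1g$v), l1l = as.numeric(L$l1l$v),
      per = as.numeric(L$per$v), sty = as.numeric(L$sty$v),
      total = as.numeric(L$total$v), perLayer = list(), weights = weights)
}

#' Train the inpainting network
#'
#' Alternates one discriminator step (least-squares objective on the global
#' image and the white-filled local region) with one generator step on the
#' full composite loss. With an adversarial weight of zero the
#' discriminators are skipped entirely and training is a deterministic
#' minimization of the pixel/perceptual/style objective.
#'
#' @param crops training list of [GlomCrop-class] objects.
#' @param weights loss weights as from [lossWeights()].
#' @param config an [inpaintTrainConfig()].
#' @param generator,discGlobal,discLocal optional prebuilt models (built
#'   fresh under `config$seed` when NULL).
#' @param phi feature extractor for the perceptual/style terms (default
#'   [convFeatureExtractor()]; set NULL to disable).
#' @param baseWidth generator width when building fresh models.
#' @param discChannels discriminator widths when building fresh models.
#' @return `list(generator, discGlobal, discLocal, log, reports)`; `log` is
#'   a per-step data frame of every loss component.
#' @export
trainInpainter <- function(crops, weights = lossWeights(),
                           config = inpaintTrainConfig(),
                           generator = NULL, discGlobal = NULL,
                           discLocal = NULL,
                           phi = convFeatureExtractor(),
                           baseWidth = 64L,
                           discChannels = c(64L, 128L, 256L, 512L, 512L, 1L)) {
  if (length(crops) == 0) stop("empty training set")
  s <- nrow(crops[[1]]@mask)
  adversarial <- weights[["adv"]] > 0
  withSeed(config$seed, {
    if (is.null(generator))
      generator <- buildGenerator(imageSize = s, baseWidth = baseWidth)
    if (adversarial && is.null(discGlobal))
      discGlobal <- buildDiscriminator(imageSize = s, channels = discChannels)
    if (adversarial && is.null(discLocal))
      discLocal <- buildDiscriminator(imageSize = s, channels = discChannels)
    optG <- adamInit(generator$params)
    discParams <- if (adversarial) c(discGlobal$params, discLocal$params)
                  else list()
    optD <- if (adversarial) adamInit(discParams) else NULL
    if (!is.null(config$logPath) && file.exists(config$logPath))
      unlink(config$logPath)
    n <- length(crops)
    bs <- min(config$batchSize, n)
    logRows <- list(); reports <- list()
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      nb <- max(1L, n %/% bs)
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * bs + 1L):min(b * bs, n)]
        batch <- cropsToBatch(crops, idx)
        dlossv <- NA_real_
        if (adversarial) {
          XrecD <- agNoGrad({
            o <- generator$forward(agTensor(batch$Xinput), training = TRUE)
            (o$v + 1) / 2
          })
          RrecD <- XrecD * batch$m3 + (1 - batch$m3)
          Rori <- batch$Xori * batch$m3 + (1 - batch$m3)
          agZeroGrad(discParams)
          sgr <- discGlobal$forward(agTensor(batch$Xori), training = TRUE)
          sgf <- discGlobal$forward(agTensor(XrecD), training = TRUE)
          slr <- discLocal$forward(agTensor(Rori), training = TRUE)
          slf <- discLocal$forward(agTensor(RrecD), training = TRUE)
          dloss <- Reduce(agAdd, list(
            agMeanAll(agSqr(sgf)), agMeanAll(agSqr(agRsubC(1, sgr))),
            agMeanAll(agSqr(slf)), agMeanAll(agSqr(agRsubC(1, slr)))))
          agBackward(dloss)
          adamStep(discParams, optD, config$lr, config$beta1, config$beta2)
          dlossv <- as.numeric(dloss$v)
        }
        agZeroGrad(generator$params)
        if (adversarial) agZeroGrad(discParams)
        L <- inpaintLossesAg(generator, batch, weights, phi,
                             training = TRUE,
                             discG = if (adversarial) discGlobal else NULL,
                             discL = if (adversarial) discLocal else NULL)
        if (!is.finite(L$total$v))
          stop(sprintf("non-finite generator loss at epoch %d step %d",
                       ep, step + 1L))
        agBackward(L$total)
        adamStep(generator$params, optG, config$lr, config$beta1,
                 config$beta2)
        step <- step + 1L
        rep <- lossReportFrom(L, weights)
        reports[[step]] <- rep
        row <- data.frame(epoch = ep, step = step, d_loss = dlossv,
                          advg = rep@advg, advl = rep@advl, l1g = rep@l1g,
                          l1l = rep@l1l, per = rep@per, sty = rep@sty,
                          total = rep@total)
        logRows[[step]] <- row
        if (!is.null(config$logPath))
          cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = NA),
              "\n",
              file = config$logPath, append = TRUE)
      }
      if (!is.null(config$checkpointDir)) {
        dir.create(config$checkpointDir, recursive = TRUE,
                   showWarnings = FALSE)
        writeCheckpoint(generator,
                        file.path(config$checkpointDir,
                                  sprintf("generator_epoch%03d.ckpt", ep)))
      }
    }
    list(generator = generator, discGlobal = discGlobal,
         discLocal = discLocal, log = do.call(rbind, logRows),
         reports = reports)
  })
}

#' Evaluate an inpainter on held-out crops
#'
#' Reconstructs each crop from its gap image and reports MAE/PSNR/SSIM both
#' over the full image and restricted to the masked glomerulus region,
#' averaged over crops.
#'
#' @param crops nonempty test list of [GlomCrop-class] objects.
#' @param generator trained generator (or a function
#'   `(InpaintSample) -> Xrec` for oracle tests).
#' @return `list(full, masked, perCrop)` of MAE/PSNR/SSIM summaries.
#' @export
evaluateInpainter <- function(crops, generator) {
  if (length(crops) == 0) stop("empty test set")
  per <- lapply(crops, function(cr) {
    sample <- makeInpaintInput(cr@image, cr@mask)
    Xrec <- runInpainter(generator, sample)
    list(full = imageQuality(cr@image, Xrec),
         masked = imageQuality(cr@image, Xrec, mask = cr@mask))
  })
  avg <- function(region, what)
    mean(vapply(per, function(p) p[[region]][[what]], numeric(1)))
  list(full = list(mae = avg("full", "mae"), psnr = avg("full", "psnr"),
                   ssim = avg("full", "ssim")),
       masked = list(mae = avg("masked", "mae"), psnr = avg("masked", "psnr"),
                     ssim = avg("masked", "ssim")),
       perCrop = per)
}

## run a generator model or an oracle function on one InpaintSample
runInpainter <- function(generator, sample) {
  if (is.function(generator)) return(generator(sample))
  tanhToUnit(generatorForward(generator, sample@Xinput, training = FALSE))
}
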