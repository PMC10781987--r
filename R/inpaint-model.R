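## The inpainting generator (encoder -> 8 AOT blocks -> self-attention ->
## decoder with skip connections, tanh output) and the PatchGAN
## discriminator used in both global and local roles.

addAOT <- function(m, name, C, dilations = c(1L, 2L, 4L, 8L),
                   gateOnResidual = FALSE) {
  nb <- length(dilations)
  if (C %% nb != 0)
    stop(sprintf("channels (%d) not divisible by branch count (%d)", C, nb))
  Cb <- C %/% nb
  branches <- lapply(seq_len(nb), function(i)
    addConv(m, sprintf("%s.branch%d", name, i), Cb, Cb, 3L,
            stride = 1L, pad = dilations[i], dil = dilations[i]))
  fuse <- addConv(m, paste0(name, ".fuse"), C, C, 1L)
  gate <- addConv(m, paste0(name, ".gate"), C, C, 3L, pad = 1L)
  function(x) {
    outs <- lapply(seq_len(nb), function(i) {
      xi <- agSliceC(x, (i - 1L) * Cb + 1L, i * Cb)
      agLeakyReLU(branches[[i]](xi), slope = 0) # ReLU
    })
    merged <- Reduce(agConcatC, outs)
    x2 <- fuse(merged)
    beta <- agSigmoid(gate(x))
    if (gateOnResidual)
      agAdd(agMul(agRsubC(1, beta), x), agMul(beta, x2))
    else
      agAdd(agMul(beta, x), agMul(agRsubC(1, beta), x2))
  }
}

#' Build one AOT (aggregated contextual transformations) block
#'
#' Split-transform-merge residual block: the input channels are split into
#' one group per dilation rate, each group is transformed by a 3x3 dilated
#' convolution + ReLU, the groups are concatenated and fused by a 1x1
#' convolution into a residual feature `x2`, and a spatially-variant gate
#' `beta = sigmoid(conv3x3(x))` mixes input and residual as
#' `beta * x + (1 - beta) * x2` (orientation flippable via
#' `gateOnResidual`).
#'
#' @param channels input/output channel count (divisible by
#'   `length(dilations)`).
#' @param dilations integer dilation rates, one per branch.
#' @param gateOnResidual logical; flip which operand receives `beta`.
#' @param seed optional RNG seed for the weights.
#' @return A model object with `$forward`; see [aotBlockForward()].
#' @export
buildAOTBlock <- function(channels, dilations = c(1L, 2L, 4L, 8L),
                          gateOnResidual = FALSE, seed = NULL) {
  build <- function() {
    m <- mkModule(list(type = "aot",
                       args = list(channels = channels, dilations = dilations,
                                   gateOnResidual = gateOnResidual,
                                   seed = seed)))
    fwd <- addAOT(m, "aot", as.integer(channels), as.integer(dilations),
                  gateOnResidual)
    m$forward <- fwd
    m
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Forward pass through an AOT block
#'
#' @param block a block from [buildAOTBlock()].
#' @param x numeric feature array `c(H, W, C)` or `c(H, W, C, N)`.
#' @return array of the same shape.
#' @export
aotBlockForward <- function(block, x) {
  d <- dim(x)
  if (length(d) == 3) x <- array(x, dim = c(d, 1))
  out <- agNoGrad(block$forward(agTensor(x)))$v
  if (length(d) == 3) array(out, dim = d) else out
}

#' Build a standalone self-attention block
#'
#' Non-local attention over all spatial positions with row-normalized
#' softmax weights and a learned output gain initialized to 0, so a freshly
#' built block is exactly the identity.
#'
#' @param channels feature channel count.
#' @param seed optional RNG seed.
#' @return A model object with `$forward`; see [selfAttentionForward()].
#' @export
buildSelfAttention <- function(channels, seed = NULL) {
  build <- function() {
    m <- mkModule(list(type = "attention",
                       args = list(channels = channels, seed = seed)))
    m$forward <- addSelfAttention(m, "att", as.integer(channels))
    m
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Forward pass through a self-attention block
#' @param block a block from [buildSelfAttention()].
#' @param x numeric feature array `c(H, W, C)` or `c(H, W, C, N)`.
#' @return array of the same shape.
#' @export
selfAttentionForward <- function(block, x) {
  d <- dim(x)
  if (length(d) == 3) x <- array(x, dim = c(d, 1))
  out <- agNoGrad(block$forward(agTensor(x)))$v
  if (length(d) == 3) array(out, dim = d) else out
}

#' Attention weight map of a self-attention block for one sample
#'
#' Returns the (HW x HW) row-stochastic attention matrix, mainly for tests
#' and inspection.
#'
#' @param block a block from [buildSelfAttention()].
#' @param x numeric feature array `c(H, W, C)`.
#' @return matrix of attention weights, rows summing to 1.
#' @export
selfAttentionWeights <- function(block, x) {
  d <- dim(x)
  agNoGrad({
    xm <- agToMat(agTensor(array(x, dim = c(d, 1))))
    q <- agMatmul(xm, block$params$att.wq)
    k <- agMatmul(xm, block$params$att.wk)
    agSoftmaxRows(agMatmulTB(q, k))$v
  })
}

#' Build the inpainting generator
#'
#' Encoder (7x7 conv + BN + LeakyReLU, then two 4x4 stride-2 convs) into a
#' stack of identically configured AOT blocks, a self-attention block at a
#' quarter of the input resolution (64x64 for 256 inputs), and a mirrored
#' decoder (two transposed convolutions with encoder skip concatenations)
#' ending in a 3-channel tanh output. RGB input channels are mapped to
#' `[-1, 1]` internally; the mask channel stays 0/1.
#'
#' @param imageSize input resolution (default 256).
#' @param baseWidth encoder width `w`; stages use `w, 2w, 4w` channels.
#' @param nAotBlocks number of AOT blocks (default 8).
#' @param aotDilations dilation rates shared by every block.
#' @param attentionAt spatial size at which self-attention runs; must equal
#'   `imageSize / 4`.
#' @param inputChannels number of input channels (3 RGB + 1 mask).
#' @param gateOnResidual flip the AOT gating orientation.
#' @param seed optional RNG seed for the weights.
#' @return A generator model; run it with [generatorForward()].
#' @export
buildGenerator <- function(imageSize = 256L, baseWidth = 64L, nAotBlocks = 8L,
                           aotDilations = c(1L, 2L, 4L, 8L),
                           attentionAt = NULL, inputChannels = 4L,
                           gateOnResidual = FALSE, seed = NULL) {
  imageSize <- as.integer(imageSize)
  if (is.null(attentionAt)) attentionAt <- imageSize %/% 4L
  if (attentionAt != imageSize %/% 4L)
    stop(sprintf("self-attention must run at %d (= imageSize/4), got %d",
                 imageSize %/% 4L, attentionAt))
  if (nAotBlocks < 1) stop("nAotBlocks must be >= 1")
  w <- as.integer(baseWidth)
  args <- list(imageSize = imageSize, baseWidth = w, nAotBlocks = nAotBlocks,
               aotDilations = aotDilations, attentionAt = attentionAt,
               inputChannels = inputChannels,
               gateOnResidual = gateOnResidual, seed = seed)
  build <- function() {
    m <- mkModule(list(type = "generator", args = args))
    enc1 <- addConv(m, "enc1", as.integer(inputChannels), w, 7L, pad = 3L)
    bn1 <- addBN(m, "enc1.bn", w)
    enc2 <- addConv(m, "enc2", w, 2L * w, 4L, stride = 2L, pad = 1L)
    bn2 <- addBN(m, "enc2.bn", 2L * w)
    enc3 <- addConv(m, "enc3", 2L * w, 4L * w, 4L, stride = 2L, pad = 1L)
    bn3 <- addBN(m, "enc3.bn", 4L * w)
    aots <- lapply(seq_len(nAotBlocks), function(i)
      addAOT(m, sprintf("aot%d", i), 4L * w, as.integer(aotDilations),
             gateOnResidual))
    att <- addSelfAttention(m, "att", 4L * w)
    dec1 <- addConvT(m, "dec1", 4L * w, 2L * w)
    dbn1 <- addBN(m, "dec1.bn", 2L * w)
    dec2 <- addConvT(m, "dec2", 4L * w, w)   # input = dec1 out + enc2 skip
    dbn2 <- addBN(m, "dec2.bn", w)
    outc <- addConv(m, "out", 2L * w, 3L, 7L, pad = 3L) # dec2 out + enc1 skip
    m$forward <- function(x, training = TRUE) {
      rgb <- agAddC(agMulC(agSliceC(x, 1L, 3L), 2), -1)
      msk <- agSliceC(x, 4L, 4L)
      x <- agConcatC(rgb, msk)
      e1 <- agLeakyReLU(bn1(enc1(x), training))
      e2 <- agLeakyReLU(bn2(enc2(e1), training))
      h <- agLeakyReLU(bn3(enc3(e2), training))
      for (blk in aots) h <- blk(h)
      m$lastAttSize <- dim(h$v)[1:2] # spatial size entering self-attention
      h <- att(h)
      d1 <- agLeakyReLU(dbn1(dec1(h), training))
      d1 <- agConcatC(d1, e2)
      d2 <- agLeakyReLU(dbn2(dec2(d1), training))
      d2 <- agConcatC(d2, e1)
      agTanh(outc(d2))
    }
    m
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Run the inpainting generator
#'
#' @param gen generator from [buildGenerator()].
#' @param Xinput numeric array `c(s, s, 4)` (or `c(s, s, 4, N)`): RGB gap
#'   image in `[0, 1]` plus 0/1 mask channel.
#' @param training logical; use batch statistics (TRUE) or running
#'   statistics (FALSE) in the normalization layers.
#' @return tanh output in `[-1, 1]`, shape `c(s, s, 3[, N])`.
#' @export
generatorForward <- function(gen, Xinput, training = FALSE) {
  d <- dim(Xinput)
  if (d[1] != gen$config$args$imageSize || d[3] != 4L)
    stop(sprintf("expected %dx%dx4 input",
                 gen$config$args$imageSize, gen$config$args$imageSize))
  if (length(d) == 3) Xinput <- array(Xinput, dim = c(d, 1))
  out <- agNoGrad(gen$forward(agTensor(Xinput), training = training))$v
  if (length(d) == 3) array(out, dim = c(d[1], d[2], 3)) else out
}

#' Map generator output from [-1, 1] to [0, 1]
#' @param x tanh-scaled raster.
#' @return raster in `[0, 1]`.
#' @export
tanhToUnit <- function(x) (x + 1) / 2

#' Build a PatchGAN discriminator
#'
#' Six 4x4 stride-2 convolutions (LeakyReLU 0.2 between; batch
#' normalization on the middle layers, none on the first and last) mapping
#' a 256x256 RGB input to a 4x4 grid of patch realness scores. The same
#' architecture serves as the global discriminator (full images) and the
#' local discriminator (white-filled glomerulus regions).
#'
#' @param imageSize input resolution (default 256; must be divisible by
#'   `2^length(channels)`).
#' @param channels output width per layer; the default widths double per stage
#'   up to 512, with the penultimate stage repeated to reach six layers.
#' @param seed optional RNG seed.
#' @return A discriminator model; run it with [discriminatorForward()].
#' @export
buildDiscriminator <- function(imageSize = 256L,
                               channels = c(64L, 128L, 256L, 512L, 512L, 1L),
                               seed = NULL) {
  imageSize <- as.integer(imageSize)
  nl <- length(channels)
  if (imageSize %% 2L^nl != 0L)
    stop("imageSize must be divisible by 2^nlayers")
  args <- list(imageSize = imageSize, channels = channels, seed = seed)
  build <- function() {
    m <- mkModule(list(type = "discriminator", args = args))
    cin <- 3L
    convs <- list(); bns <- list()
    for (i in seq_len(nl)) {
      convs[[i]] <- addConv(m, sprintf("conv%d", i), cin,
                            as.integer(channels[i]), 4L, stride = 2L,
                            pad = 1L)
      if (i > 1 && i < nl) bns[[i]] <- addBN(m, sprintf("bn%d", i),
                                             as.integer(channels[i]))
      cin <- as.integer(channels[i])
    }
    m$forward <- function(x, training = TRUE) {
      h <- agAddC(agMulC(x, 2), -1)
      for (i in seq_len(nl)) {
        h <- convs[[i]](h)
        if (i < nl) {
          h <- agLeakyReLU(h, 0.2)
          if (i > 1) h <- bns[[i]](h, training)
        }
      }
      h
    }
    m
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

#' Run a PatchGAN discriminator
#'
#' @param disc discriminator from [buildDiscriminator()].
#' @param x numeric array `c(s, s, 3)` or `c(s, s, 3, N)` in `[0, 1]`.
#' @param training use batch (TRUE) or running (FALSE) normalization
#'   statistics.
#' @return patch score map `c(n, n)` or `c(n, n, 1, N)`.
#' @export
discriminatorForward <- function(disc, x, training = FALSE) {
  d <- dim(x)
  s <- disc$config$args$imageSize
  if (d[1] != s || d[2] != s || d[3] != 3L)
    stop(sprintf("expected %dx%dx3 input", s, s))
  if (length(d) == 3) x <- array(x, dim = c(d, 1))
  out <- agNoGrad(disc$forward(agTensor(x), training = training))$v
  if (length(d) == 3) matrix(out[, , 1, 1], nrow = dim(out)[1]) else out
}

#' Total parameter count of a model
#' @param model any model built by this package.
#' @return integer number of scalar parameters.
#' @export
parameterCount <- function(model) {
  sum(vapply(model$params, function(p) length(p$v), numeric(1)))
}
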