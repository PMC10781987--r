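# Architecture contracts of the generator, AOT blocks, self-attention and
# PatchGAN discriminators (desk-scale widths; geometry is width-independent).

test_that("generator maps s x s x 4 to s x s x 3 in [-1, 1]", {
  g <- buildGenerator(imageSize = 64, baseWidth = 4, nAotBlocks = 2, seed = 7)
  x <- array(runif(64 * 64 * 4), dim = c(64, 64, 4))
  out <- generatorForward(g, x, training = TRUE)
  expect_equal(dim(out), c(64, 64, 3))
  expect_true(all(out >= -1 & out <= 1))
  # attention runs at a quarter of the input resolution
  expect_equal(g$lastAttSize, c(16, 16))
  # batching
  xb <- array(runif(64 * 64 * 4 * 3), dim = c(64, 64, 4, 3))
  outb <- generatorForward(g, xb, training = TRUE)
  expect_equal(dim(outb), c(64, 64, 3, 3))
})

test_that("generator builds are deterministic under a seed", {
  g1 <- buildGenerator(imageSize = 64, baseWidth = 4, nAotBlocks = 2, seed = 3)
  g2 <- buildGenerator(imageSize = 64, baseWidth = 4, nAotBlocks = 2, seed = 3)
  expect_equal(parameterCount(g1), parameterCount(g2))
  expect_identical(glomopaint:::moduleValues(g1),
                   glomopaint:::moduleValues(g2))
  expect_error(buildGenerator(imageSize = 256, attentionAt = 32), "64")
  expect_error(buildGenerator(imageSize = 64, nAotBlocks = 0), "nAotBlocks")
})

test_that("AOT blocks preserve shape for dilations 1/2/4/8 and gate as specified", {
  blk <- buildAOTBlock(8, dilations = c(1, 2, 4, 8), seed = 5)
  x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  out <- aotBlockForward(blk, x)
  expect_equal(dim(out), dim(x))
  expect_error(buildAOTBlock(6, dilations = c(1, 2, 4, 8)), "divisible")

  # zero gate conv => beta = 0.5 everywhere => out = 0.5 x1 + 0.5 x2,
  # identical under either gating orientation
  for (nm in c("aot.gate.w", "aot.gate.b")) blk$params[[nm]]$v[] <- 0
  blkF <- buildAOTBlock(8, dilations = c(1, 2, 4, 8), gateOnResidual = TRUE,
                        seed = 5)
  for (nm in c("aot.gate.w", "aot.gate.b")) blkF$params[[nm]]$v[] <- 0
  expect_equal(aotBlockForward(blk, x), aotBlockForward(blkF, x),
               tolerance = 1e-12)

  # large positive gate bias => beta ~ 1 => out ~ x1 (input orientation)
  blk$params$aot.gate.b$v[] <- 50
  expect_lt(max(abs(aotBlockForward(blk, x) - x)), 1e-6)

  # gradient reaches every branch
  blk2 <- buildAOTBlock(8, seed = 6)
  xt <- glomopaint:::agTensor(array(rnorm(8 * 8 * 8), c(8, 8, 8, 1)))
  glomopaint:::agBackward(glomopaint:::agMeanAll(glomopaint:::agSqr(
    blk2$forward(xt))))
  for (i in 1:4) {
    gw <- blk2$params[[sprintf("aot.branch%d.w", i)]]$grad
    expect_false(is.null(gw))
    expect_gt(max(abs(gw)), 0)
  }
})

test_that("self-attention is the identity at build time and row-stochastic", {
  blk <- buildSelfAttention(8, seed = 9)
  x <- array(rnorm(4 * 4 * 8), dim = c(4, 4, 8))
  expect_equal(selfAttentionForward(blk, x), x) # gamma initialized to 0
  A <- selfAttentionWeights(blk, x)
  expect_equal(rowSums(A), rep(1, 16), tolerance = 1e-5)

  # permutation equivariance: permuting spatial positions permutes outputs
  blk$params$att.gamma$v <- 0.5
  d <- dim(x)
  xm <- matrix(x, nrow = 16, ncol = 8)
  perm <- sample(16)
  xp <- array(xm[perm, ], dim = d)
  outm <- matrix(selfAttentionForward(blk, x), nrow = 16)
  outp <- matrix(selfAttentionForward(blk, xp), nrow = 16)
  expect_equal(outp, outm[perm, ], tolerance = 1e-10)
})

test_that("whole generator at zero attention gain equals its ablation", {
  g <- buildGenerator(imageSize = 64, baseWidth = 4, nAotBlocks = 2, seed = 13)
  expect_equal(g$params$att.gamma$v, 0)
  x <- array(runif(64 * 64 * 4), dim = c(64, 64, 4))
  ref <- generatorForward(g, x, training = TRUE)
  # scrambling attention weights must not matter while gamma = 0
  g$params$att.wv$v <- g$params$att.wv$v + 1
  expect_equal(generatorForward(g, x, training = TRUE), ref)
})

test_that("discriminator yields an N x N patch score map", {
  d <- buildDiscriminator(imageSize = 256,
                          channels = c(8, 16, 32, 64, 64, 1), seed = 7)
  x <- array(runif(256 * 256 * 3), dim = c(256, 256, 3))
  sc <- discriminatorForward(d, x, training = TRUE)
  expect_equal(dim(sc), c(4, 4)) # 256 / 2^6
  expect_error(discriminatorForward(d, array(0.5, c(64, 64, 3))), "expected")

  d2 <- buildDiscriminator(imageSize = 256,
                           channels = c(8, 16, 32, 64, 64, 1), seed = 7)
  expect_equal(discriminatorForward(d2, x, training = TRUE), sc)

  xb <- array(runif(256 * 256 * 3 * 2), dim = c(256, 256, 3, 2))
  scb <- discriminatorForward(d, xb, training = TRUE)
  expect_equal(dim(scb), c(4, 4, 1, 2))
})

test_that("every generator parameter group receives gradient", {
  g <- buildGenerator(imageSize = 32, baseWidth = 4, nAotBlocks = 2,
                      attentionAt = 8, seed = 15)
  g$params$att.gamma$v <- 0.1 # open the attention path
  x <- glomopaint:::agTensor(array(runif(32 * 32 * 4 * 2), c(32, 32, 4, 2)))
  out <- g$forward(x, training = TRUE)
  glomopaint:::agBackward(glomopaint:::agMeanAll(glomopaint:::agSqr(out)))
  groups <- list(encoder = "^enc", aot = "^aot", attention = "^att",
                 decoder = "^dec|^out")
  for (gn in names(groups)) {
    nms <- grep(groups[[gn]], names(g$params), value = TRUE)
    gmax <- max(vapply(nms, function(nm) {
      gr <- g$params[[nm]]$grad
      if (is.null(gr)) 0 else max(abs(gr))
    }, numeric(1)))
    expect_gt(gmax, 0)
    finite <- all(vapply(nms, function(nm) {
      gr <- g$params[[nm]]$grad
      is.null(gr) || all(is.finite(gr))
    }, logical(1)))
    expect_true(finite)
  }
})

test_that("checkpoints round-trip weights and configuration", {
  g <- buildGenerator(imageSize = 64, baseWidth = 4, nAotBlocks = 2, seed = 21)
  x <- array(runif(64 * 64 * 4), dim = c(64, 64, 4))
  ref <- generatorForward(g, x, training = FALSE)
  path <- tempfile(fileext = ".ckpt")
  writeCheckpoint(g, path)
  g2 <- readCheckpoint(path)
  expect_equal(generatorForward(g2, x, training = FALSE), ref)
  unlink(path)
})
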