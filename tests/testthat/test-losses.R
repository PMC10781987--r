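# The composite inpainting loss and the segmentation loss.

test_that("gap/input construction follows the pixelwise definition", {
  Xori <- array(0.5, dim = c(2, 2, 3))
  Xmask <- matrix(c(1, 0, 0, 1), 2) # column-major: (1,1) and (2,2)
  s <- makeInpaintInput(Xori, Xmask)
  expect_equal(s@Xgap[, , 1], matrix(c(0, 0.5, 0.5, 0), 2))
  expect_equal(s@Xinput[, , 4], Xmask)
  expect_equal(dim(s@Xinput), c(2, 2, 4))

  s0 <- makeInpaintInput(Xori, matrix(0, 2, 2))
  expect_equal(s0@Xgap, Xori)
  s1 <- makeInpaintInput(Xori, matrix(1, 2, 2))
  expect_equal(s1@Xgap, Xori * 0)
  expect_error(makeInpaintInput(Xori, matrix(0, 3, 3)), "mismatch")
  expect_error(makeInpaintInput(Xori, matrix(0.5, 2, 2)), "binary")
})

test_that("local region white-fills the background", {
  X <- matrix(0.25, 2, 2)
  mask <- matrix(c(1, 0, 0, 0), 2)
  expect_equal(localRegion(X, mask), matrix(c(0.25, 1, 1, 1), 2))
  expect_equal(localRegion(X, matrix(0, 2, 2)), matrix(1, 2, 2))
  expect_equal(localRegion(X, matrix(1, 2, 2)), X)
  # 3-channel broadcasting
  X3 <- array(0.25, dim = c(2, 2, 3))
  R3 <- localRegion(X3, mask)
  expect_equal(R3[1, 1, ], rep(0.25, 3))
  expect_equal(R3[2, 2, ], rep(1, 3))
})

test_that("least-squares adversarial losses match hand evaluation", {
  z <- matrix(0, 4, 4); o <- matrix(1, 4, 4)
  expect_equal(adversarialLosses(Dreal = o, Dfake = z)$discriminator, 0)
  expect_equal(adversarialLosses(Dreal = o, Dfake = o)$discriminator, 1)
  expect_equal(adversarialLosses(Dreal = o, Dfake = z + 0.5)$generator, 0.25)
  expect_error(adversarialLosses(matrix(0, 2, 2), matrix(0, 3, 3)),
               "mismatch")
})

test_that("pixel losses vanish at identity and localize to the mask", {
  cr <- makeFixtureCrops(1, size = 64, seed = 3)[[1]]
  s <- makeInpaintInput(cropImage(cr), cropMask(cr))
  l0 <- l1Losses(s, s@Xori)
  expect_equal(l0$l1g, 0); expect_equal(l0$l1l, 0)

  shifted <- s@Xori + 0.1 # unclamped constant shift
  l1 <- l1Losses(s, shifted)
  expect_equal(l1$l1g, 0.1, tolerance = 1e-12)

  # change only outside the mask: local loss stays zero
  out <- s@Xori
  m3 <- array(rep(cropMask(cr), 3), dim = dim(out))
  out <- out + 0.2 * (1 - m3)
  l2 <- l1Losses(s, out)
  expect_equal(l2$l1l, 0)
  expect_gt(l2$l1g, 0)
})

test_that("perceptual and style losses use the injected extractor", {
  set.seed(4)
  a <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))
  b <- pmin(pmax(a + rnorm(length(a), 0, 0.05), 0), 1)
  idf <- identityFeatureExtractor()
  ps0 <- perceptualAndStyle(a, a, idf)
  expect_equal(ps0$per, 0); expect_equal(ps0$sty, 0)
  ps <- perceptualAndStyle(a, b, idf)
  expect_equal(ps$per, mean(abs(a - b)))
  expect_error(perceptualAndStyle(a, b, idf, layers = "missing"), "unknown")

  phi <- convFeatureExtractor(seed = 99)
  psc <- perceptualAndStyle(a, a, phi)
  expect_equal(psc$per, 0); expect_equal(psc$sty, 0)
  expect_length(perceptualAndStyle(a, b, phi)$perLayer$per, 3)
})

test_that("Gram matrix of a constant map matches a hand loop", {
  n <- 16 * 16
  cmap <- array(0.3, dim = c(16, 16, 1))
  G <- glomopaint:::gramMatrix(cmap)
  # hand loop with the same element-count normalization
  Fm <- matrix(cmap, ncol = 1)
  hand <- 0
  for (i in seq_len(nrow(Fm))) hand <- hand + Fm[i, 1] * Fm[i, 1]
  expect_equal(as.numeric(G), hand / n)
  expect_equal(as.numeric(G), 0.3^2)
  # two-channel case against the loop
  set.seed(5)
  f2 <- array(runif(8 * 8 * 2), dim = c(8, 8, 2))
  G2 <- glomopaint:::gramMatrix(f2)
  Fm2 <- matrix(f2, ncol = 2)
  expect_equal(G2, crossprod(Fm2) / length(f2))
})

test_that("the weighted total matches hand evaluation of the printed weights", {
  r0 <- totalInpaintLoss(0, 0, 0, 0, 0, 0)
  expect_equal(r0@total, 0)
  r1 <- totalInpaintLoss(1, 1, 1, 1, 1, 1)
  expect_equal(r1@total, 0.02 * 2 + 1 + 1 + 0.1 + 150) # = 152.14
  expect_equal(r1@total, 152.14)
  r2 <- totalInpaintLoss(1, 1, 0, 0, 0, 0)
  expect_equal(r2@total, 0.04)
  expect_error(totalInpaintLoss(-1, 0, 0, 0, 0, 0), "negative")
  expect_error(totalInpaintLoss(NaN, 0, 0, 0, 0, 0), "finite")
})

test_that("the total is linear in each component with its weight", {
  set.seed(6)
  base <- runif(6)
  w <- lossWeights()
  slopes <- c(w[["adv"]], w[["adv"]], w[["l1g"]], w[["l1l"]], w[["per"]],
              w[["sty"]])
  for (i in 1:6) {
    up <- base; up[i] <- up[i] + 1
    d <- do.call(totalInpaintLoss, as.list(up))@total -
      do.call(totalInpaintLoss, as.list(base))@total
    expect_equal(d, slopes[i], tolerance = 1e-10)
  }
})

test_that("segmentation loss combines BCE and soft Dice as specified", {
  t <- matrix(rep(c(1, 0), each = 8), 4)
  pEx <- pmin(pmax(t, 1e-7), 1 - 1e-7)
  expect_lt(segLoss(pEx, t), 1e-5)

  p5 <- matrix(0.5, 4, 4)
  # BCE = ln 2; soft Dice = 0.5 -> loss = 0.5*ln2 + 0.5
  expect_equal(segLoss(p5, t), 0.5 * log(2) + 0.5, tolerance = 1e-5)
  expect_equal(segLoss(p5, t, lambda = 0),
               1 - (2 * 0.25 * 16) / (0.5 * 16 + 0.5 * 16 + 1e-6),
               tolerance = 1e-5)
  expect_error(segLoss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "mismatch")
})
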