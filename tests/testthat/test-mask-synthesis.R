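# Mask post-processing, contour rescaling, size balancing and the DCGAN
# sampler contracts.

test_that("post-processing binarizes and removes small regions", {
  expect_equal(sum(maskRaster(postprocessMask(matrix(0, 32, 32)))), 0)

  raw <- matrix(0, 32, 32)
  raw[3:4, 3:7] <- 1 # area 10
  pm <- postprocessMask(raw, minArea = 20)
  expect_equal(sum(maskRaster(pm)), 0)

  raw2 <- raw
  raw2[10:31, 10:31] <- 1 # area 484
  pm2 <- postprocessMask(raw2, minArea = 20)
  expect_equal(sum(maskRaster(pm2)), 484) # only the big blob survives
  expect_equal(provenance(pm2), "postprocessed")
  expect_equal(oracleComponentAreas(maskRaster(pm2)), 484)

  # 3-channel input goes through luma first
  col <- array(0, dim = c(16, 16, 3))
  col[4:12, 4:12, 1] <- 1; col[4:12, 4:12, 2] <- 1; col[4:12, 4:12, 3] <- 1
  expect_equal(sum(maskRaster(postprocessMask(col, minArea = 10))), 81)
  expect_error(postprocessMask(matrix(NaN, 4, 4)), "finite")
})

test_that("post-processing is idempotent", {
  set.seed(31)
  raw <- matrix(runif(64 * 64), 64)
  p1 <- postprocessMask(raw, minArea = 30)
  p2 <- postprocessMask(maskRaster(p1), minArea = 30)
  expect_equal(maskRaster(p2), maskRaster(p1))
})

test_that("contour rescaling scales areas about fixed centroids", {
  da <- MaskArtifact(blobMask(256, 256, 128, 128, 20))
  expect_identical(rescaleContours(da, 1), da)

  half <- rescaleContours(da, 0.5)
  expect_equal(provenance(half), "scaled")
  expect_equal(scaleFactor(half), 0.5)
  expect_equal(sum(maskRaster(half)) / sum(maskRaster(da)), 0.25,
               tolerance = 0.05)

  sq <- matrix(0, 64, 64); sq[28:37, 28:37] <- 1 # centred 10x10 square
  sa <- MaskArtifact(sq)
  doubled <- rescaleContours(sa, 2)
  m <- maskRaster(doubled)
  expect_equal(sum(m), 400, tolerance = 0.05 * 400)
  c0 <- c(sum(col(sq) * sq), sum(row(sq) * sq)) / sum(sq)
  c1 <- c(sum(col(m) * m), sum(row(m) * m)) / sum(m)
  expect_lt(max(abs(c1 - c0)), 1)

  expect_error(rescaleContours(da, -1), "positive")
  expect_warning(rescaleContours(MaskArtifact(blobMask(64, 64, 50, 50, 10)), 3),
                 "clipped")
})

test_that("rescale round trip recovers component areas within 10%", {
  set.seed(33)
  for (f in c(0.6, 0.8, 1.4)) {
    da <- MaskArtifact(blobMask(256, 256, 120, 140, 25))
    rt <- rescaleContours(rescaleContours(da, f), 1 / f)
    expect_equal(sum(maskRaster(rt)), sum(maskRaster(da)),
                 tolerance = 0.1 * sum(maskRaster(da)))
  }
})

test_that("size balancing equalizes bin counts via rescaling", {
  masks <- lapply(1:10, function(i) MaskArtifact(blobMask(r = 15)))
  one <- balanceSizeDistribution(masks, list(c(1, 1e5)), seed = 1)
  expect_length(one, 10)
  expect_true(all(vapply(one, provenance, character(1)) == "real"))

  bal <- balanceSizeDistribution(masks, list(c(500, 1500), c(50, 499)),
                                 seed = 1)
  areas <- vapply(bal, function(m) sum(maskRaster(m)), numeric(1))
  inBin1 <- sum(areas >= 500 & areas <= 1500)
  inBin2 <- sum(areas >= 50 & areas < 500)
  expect_lte(abs(inBin1 - inBin2), 1)
  moved <- vapply(bal, provenance, character(1)) == "scaled"
  expect_equal(sum(moved), inBin2)

  expect_error(balanceSizeDistribution(list(), list(c(0, 10))), "empty")
  expect_error(balanceSizeDistribution(masks, list()), "empty")
  expect_error(
    suppressWarnings(balanceSizeDistribution(
      masks, list(c(500, 1500), c(1e5, 2e5)), seed = 1)),
    "unreachable")
})

test_that("mask generator sampling respects its output contract", {
  g <- buildMaskGenerator(latentDim = 8, baseWidth = 8, seed = 41)
  sm <- sampleMasks(g, 10, seed = 2, outSize = 64)
  expect_length(sm, 10)
  for (m in sm) {
    expect_equal(dim(m), c(64, 64))
    expect_true(all(m >= 0 & m <= 1))
  }
  up <- sampleMasks(g, 1, seed = 2, outSize = 256)
  expect_equal(dim(up[[1]]), c(256, 256))
  # same seed, same samples
  expect_equal(sampleMasks(g, 3, seed = 5), sampleMasks(g, 3, seed = 5))
})

test_that("GAN training is deterministic under a fixed seed", {
  real <- lapply(1:16, function(i) blobMask(r = 8 + i %% 5))
  cfg <- maskGANConfig(latentDim = 8, baseWidth = 8, batchSize = 8,
                       epochs = 2, seed = 5)
  a <- trainMaskGAN(real, cfg)
  b <- trainMaskGAN(real, cfg)
  expect_identical(a$log, b$log)
  expect_identical(glomopaint:::moduleValues(a$generator),
                   glomopaint:::moduleValues(b$generator))
  expect_error(trainMaskGAN(list(), cfg), "empty")
  expect_error(trainMaskGAN(real[1:4], cfg), "batchSize")
})

test_that("a briefly trained DCGAN matches real foreground statistics", {
  ## blob masks of varying size/position; oracle = their foreground mean
  real <- lapply(1:40, function(i)
    blobMask(64, 64, cx = 24 + (i %% 5), cy = 24 + (i %% 7),
             r = 8 + (i %% 10)))
  realFF <- mean(vapply(real, mean, numeric(1)))
  res <- trainMaskGAN(real, maskGANConfig(latentDim = 16, baseWidth = 16,
                                          batchSize = 8, epochs = 100,
                                          seed = 5))
  sm <- sampleMasks(res$generator, 20, seed = 9, outSize = 64)
  fakeFF <- mean(vapply(sm, function(m) mean(m > 0.5), numeric(1)))
  expect_gt(fakeFF, 0.5 * realFF)
  expect_lt(fakeFF, 2 * realFF)
})

test_that("every artifact leaving post-processing satisfies the min-area rule", {
  set.seed(43)
  for (i in 1:5) {
    raw <- matrix(runif(64 * 64) > 0.55, 64) * 1
    pm <- postprocessMask(raw, minArea = 15)
    areas <- oracleComponentAreas(maskRaster(pm))
    if (length(areas) > 0) expect_true(all(areas >= 15))
  }
})
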