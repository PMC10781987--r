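# Slide preprocessing: downsampling, rasterization, tiling, crops.

mkSlide <- function(H, W, anns = list()) {
  AnnotatedSlide(array(0.5, dim = c(H, W, 3)), anns)
}

squareAnn <- function(x0, y0, x1, y1, label = "sclerosed") {
  list(polygon = cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)), label = label)
}

test_that("downsampling divides raster and polygon coordinates", {
  sl <- mkSlide(64, 64, list(squareAnn(10, 10, 20, 20)))
  expect_identical(downsampleSlide(sl, 1), sl)
  img <- array(runif(2048 * 64 * 3) * 0, dim = c(64, 2048, 3))
  big <- AnnotatedSlide(array(0.3, dim = c(2048, 2048, 3)),
                        list(list(polygon = cbind(c(300, 400, 400),
                                                  c(300, 300, 400)),
                                  label = "normal")))
  ds <- downsampleSlide(big, 2)
  expect_equal(dim(slideImage(ds)), c(1024, 1024, 3))
  expect_equal(annotations(ds)[[1]]$polygon[1, ], c(150, 150))
  expect_error(downsampleSlide(mkSlide(300, 300), 400), "larger")
})

test_that("downsampling is an area (block) mean", {
  set.seed(7)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  sl <- AnnotatedSlide(img)
  ds <- downsampleSlide(sl, 4)
  expect_equal(slideImage(ds)[1, 1, 2], mean(img[1:4, 1:4, 2]))
  expect_equal(slideImage(ds)[2, 2, 3], mean(img[5:8, 5:8, 3]))
})

test_that("rasterization matches a brute-force point-in-polygon scan", {
  sl <- mkSlide(32, 32)
  expect_equal(rasterizeAnnotations(sl),
               list(maskNormal = matrix(0, 32, 32),
                    maskSclerosed = matrix(0, 32, 32)))

  ann <- squareAnn(10, 10, 20, 20)
  sl2 <- mkSlide(32, 32, list(ann))
  ms <- rasterizeAnnotations(sl2)
  expect_equal(sum(ms$maskNormal), 0)
  expect_equal(ms$maskSclerosed, oracleFillPolygon(32, 32, ann$polygon))
  expect_equal(sum(ms$maskSclerosed), 121) # 11 x 11 boundary-inclusive

  tri <- list(polygon = cbind(c(2, 9, 5), c(25, 25, 30)), label = "normal")
  sl3 <- mkSlide(32, 32, list(ann, tri))
  ms3 <- rasterizeAnnotations(sl3)
  expect_equal(ms3$maskNormal, oracleFillPolygon(32, 32, tri$polygon))
  expect_gt(sum(ms3$maskNormal), 0)
  expect_equal(sum(ms3$maskNormal * ms3$maskSclerosed), 0)
})

test_that("degenerate polygons are skipped and class overlap resolves sclerosed", {
  degen <- list(polygon = cbind(c(5, 5), c(5, 5)), label = "normal")
  expect_warning(ms <- rasterizeAnnotations(mkSlide(16, 16, list(degen))),
                 "degenerate")
  expect_equal(sum(ms$maskNormal), 0)

  a <- squareAnn(4, 4, 10, 10, "normal")
  b <- squareAnn(8, 8, 14, 14, "sclerosed")
  expect_warning(ms2 <- rasterizeAnnotations(mkSlide(20, 20, list(a, b))),
                 "sclerosed")
  expect_equal(sum(ms2$maskNormal * ms2$maskSclerosed), 0)
  expect_equal(ms2$maskSclerosed[9 + 1, 9 + 1], 1) # overlap pixel
  expect_equal(ms2$maskNormal[9 + 1, 9 + 1], 0)
})

test_that("overlapped tiling enumerates the expected window origins", {
  img <- array(0.5, dim = c(256, 256, 3))
  t1 <- tileWithOverlap(img, window = 256, stride = 128)
  expect_length(t1, 1)
  expect_equal(tileOrigin(t1[[1]]), c(0L, 0L))

  img2 <- array(0.5, dim = c(512, 512, 3))
  t9 <- tileWithOverlap(img2, window = 256, stride = 128)
  expect_length(t9, 9)
  origins <- t(vapply(t9, tileOrigin, integer(2)))
  expect_setequal(paste(origins[, 1], origins[, 2]),
                  paste(rep(c(0, 128, 256), 3), rep(c(0, 128, 256), each = 3)))

  img3 <- array(0.5, dim = c(256, 384, 3)) # W = 1.5 * window
  t2 <- tileWithOverlap(img3, window = 256, stride = 128)
  expect_length(t2, 2)
  expect_equal(lapply(t2, tileOrigin), list(c(0L, 0L), c(128L, 0L)))
})

test_that("tiling covers every pixel and pads small inputs by reflection", {
  img <- array(seq_len(300 * 200 * 3) / (300 * 200 * 3), dim = c(300, 200, 3))
  tiles <- tileWithOverlap(img, window = 128, stride = 96)
  cover <- matrix(0, 300, 200)
  for (t in tiles) {
    o <- tileOrigin(t)
    cover[(o[2] + 1):(o[2] + 128), (o[1] + 1):(o[1] + 128)] <- 1
  }
  expect_true(all(cover == 1))

  small <- array(0.2, dim = c(50, 70, 3))
  ts <- tileWithOverlap(small, window = 128, stride = 64)
  expect_length(ts, 1)
  expect_equal(dim(ts[[1]]@image), c(128, 128, 3))
})

test_that("minimum enclosing circle is exact on known geometry", {
  sq <- cbind(c(250, 350, 350, 250), c(250, 250, 350, 350))
  mec <- minEnclosingCircle(sq)
  expect_equal(mec$centre, c(300, 300))
  expect_equal(mec$radius, 50 * sqrt(2))

  # equilateral triangle: centre = circumcentre, radius = circumradius
  s <- 60
  tri <- cbind(c(0, s, s / 2), c(0, 0, s * sqrt(3) / 2))
  mec2 <- minEnclosingCircle(tri)
  expect_equal(mec2$centre, c(s / 2, s / (2 * sqrt(3))), tolerance = 1e-8)
  expect_equal(mec2$radius, s / sqrt(3), tolerance = 1e-8)

  expect_equal(minEnclosingCircle(cbind(100, 100)),
               list(centre = c(100, 100), radius = 0))
})

test_that("minimum enclosing circle contains all points and is minimal", {
  set.seed(42)
  for (rep in 1:20) {
    pts <- matrix(runif(2 * sample(3:12, 1), 0, 100), ncol = 2)
    mec <- minEnclosingCircle(pts)
    d <- sqrt(rowSums(sweep(pts, 2, mec$centre)^2))
    expect_true(all(d <= mec$radius + 1e-7))
    # minimality: radius no larger than any 2-point or 3-point candidate
    # circle that contains all points (brute force)
    best <- Inf
    n <- nrow(pts)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      ctr <- (pts[i, ] + pts[j, ]) / 2
      r <- sqrt(sum((pts[i, ] - ctr)^2))
      if (all(sqrt(rowSums(sweep(pts, 2, ctr)^2)) <= r + 1e-9))
        best <- min(best, r)
    }
    if (n >= 3)
      for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
        c3 <- glomopaint:::circleFrom3(pts[i, ], pts[j, ], pts[k, ])
        if (is.null(c3)) next
        if (all(sqrt(rowSums(sweep(pts, 2, c3$centre)^2)) <= c3$radius + 1e-9))
          best <- min(best, c3$radius)
      }
    expect_equal(mec$radius, best, tolerance = 1e-6)
  }
})

test_that("glomerulus crops are centred on the enclosing circle", {
  sl <- mkSlide(600, 600, list(squareAnn(250, 250, 350, 350)))
  cr <- extractGlomCrop(sl, 1, crop = 256)
  expect_equal(cr@centre, c(300, 300))
  expect_equal(dim(cropImage(cr)), c(256, 256, 3))
  # crop box [172, 428): mask support must sit at offset 250-172 = 78
  expect_equal(sum(cropMask(cr)), 101 * 101) # boundary-inclusive square
  expect_equal(range(which(rowSums(cropMask(cr)) > 0)), c(79, 179))
  expect_false(cr@truncated)

  # degenerate point cluster: crop translated inward, not padded
  pt <- list(polygon = cbind(c(100, 100, 100), c(100, 100, 100)),
             label = "sclerosed")
  sl2 <- mkSlide(600, 600, list(pt))
  cr2 <- extractGlomCrop(sl2, 1, crop = 256)
  expect_equal(cr2@centre, c(100, 100))
  expect_equal(cr2@radius, 0)

  # oversized glomerulus flagged, not dropped
  big <- squareAnn(50, 50, 450, 450)
  cr3 <- extractGlomCrop(mkSlide(600, 600, list(big)), 1, crop = 256)
  expect_true(cr3@truncated)
})

test_that("crop centroid tracks the crop centre when unclamped", {
  sl <- makeFixtureSlide(512, 512, 0, 3, seed = 17)
  idx <- which(vapply(annotations(sl), function(a) a$label == "sclerosed",
                      logical(1)))
  for (i in idx) {
    cr <- extractGlomCrop(sl, i, crop = 256)
    m <- cropMask(cr)
    cy <- sum(row(m) * m) / sum(m) - 1
    cx <- sum(col(m) * m) / sum(m) - 1
    expect_lt(abs(cx - 128) + abs(cy - 128), 128 + cr@radius)
  }
})
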