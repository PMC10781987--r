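## Deterministic synthetic-histology fixtures.
##
## The generator emulates PAS-like tiles qualitatively: a textured pink
## tissue field with a white (non-tissue) border margin, "normal" glomeruli
## as ellipses with dotted dark-purple interior texture (high interior
## variance) and "sclerosed" glomeruli as smooth homogeneous dark ellipses
## (low interior variance), plus matching polygon annotations. The two
## classes are separable by interior variance by construction, which is what
## lets tiny networks overfit them in the training smoke checks.

PAS_PINK <- c(0.93, 0.74, 0.85)
PAS_PURPLE_LIGHT <- c(0.76, 0.60, 0.80)
PAS_PURPLE_DARK <- c(0.42, 0.24, 0.50)
SCLEROSED_FILL <- c(0.58, 0.44, 0.60)

smoothNoise <- function(H, W, coarse = 8L, sd = 1) {
  h <- max(2L, H %/% coarse); w <- max(2L, W %/% coarse)
  z <- array(stats::rnorm(h * w, 0, sd), dim = c(h, w, 1))
  cpp_resize_bilinear(z, H, W)[, , 1]
}

ellipsePolygon <- function(cx, cy, a, b, theta = 0, n = 48L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(theta) - y * sin(theta),
        cy + x * sin(theta) + y * cos(theta))
}

paintGlom <- function(img, fill, label) {
  idx <- which(fill > 0)
  if (length(idx) == 0) return(img)
  H <- dim(img)[1]
  n <- length(idx)
  if (label == "sclerosed") {
    base <- SCLEROSED_FILL
    for (c in 1:3)
      img[idx + (c - 1) * H * dim(img)[2]] <-
        base[c] + stats::rnorm(n, 0, 0.012)
  } else {
    base <- PAS_PURPLE_LIGHT
    dots <- stats::runif(n) < 0.22
    for (c in 1:3) {
      v <- base[c] + stats::rnorm(n, 0, 0.03)
      v[dots] <- PAS_PURPLE_DARK[c] + stats::rnorm(sum(dots), 0, 0.04)
      img[idx + (c - 1) * H * dim(img)[2]] <- v
    }
  }
  img
}

#' Generate a synthetic annotated histology slide
#'
#' Deterministic under `seed`: a pink-noise tissue field with a white border
#' margin, `n_normal` dotted-texture and `n_sclerosed` homogeneous dark
#' elliptical glomeruli placed without overlap, and matching polygon
#' annotations.
#'
#' @param width,height raster size in pixels (>= 256).
#' @param n_normal,n_sclerosed glomerulus counts per class.
#' @param seed integer RNG seed.
#' @param radius_range min/max ellipse semi-axes in pixels.
#' @param margin white non-tissue border width (default 6% of the short
#'   side, at least 16 px).
#' @return An [AnnotatedSlide-class].
#' @export
makeFixtureSlide <- function(width = 512L, height = 512L, n_normal = 2L,
                             n_sclerosed = 2L, seed = 1L,
                             radius_range = c(20, 44), margin = NULL) {
  stopifnot(width >= 256, height >= 256, n_normal >= 0, n_sclerosed >= 0)
  withSeed(seed, {
    H <- as.integer(height); W <- as.integer(width)
    if (is.null(margin)) margin <- max(16L, as.integer(0.06 * min(H, W)))
    img <- array(0, dim = c(H, W, 3))
    for (c in 1:3)
      img[, , c] <- PAS_PINK[c] + 0.05 * smoothNoise(H, W) +
        stats::rnorm(H * W, 0, 0.015)
    ## white non-tissue margin
    border <- matrix(FALSE, H, W)
    border[c(seq_len(margin), H - seq_len(margin) + 1L), ] <- TRUE
    border[, c(seq_len(margin), W - seq_len(margin) + 1L)] <- TRUE
    nb <- sum(border)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[border] <- 0.975 + stats::rnorm(nb, 0, 0.005)
      img[, , c] <- ch
    }
    labels <- c(rep("normal", n_normal), rep("sclerosed", n_sclerosed))
    anns <- list()
    placed <- matrix(0, H, W)
    for (i in seq_along(labels)) {
      ok <- FALSE
      for (try in 1:200) {
        a <- stats::runif(1, radius_range[1], radius_range[2])
        b <- stats::runif(1, radius_range[1], radius_range[2])
        th <- stats::runif(1, 0, pi)
        r <- max(a, b)
        cx <- stats::runif(1, margin + r + 2, W - 1 - margin - r - 2)
        cy <- stats::runif(1, margin + r + 2, H - 1 - margin - r - 2)
        poly <- ellipsePolygon(cx, cy, a, b, th)
        fill <- cpp_fill_polygon(H, W, poly[, 1], poly[, 2])
        if (sum(fill * placed) == 0) {
          placed <- pmax(placed, fill)
          img <- paintGlom(img, fill, labels[i])
          anns[[length(anns) + 1L]] <- list(polygon = poly, label = labels[i])
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop(sprintf("could only place %d of %d glomeruli without overlap",
                     length(anns), length(labels)))
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    AnnotatedSlide(img, anns)
  })
}

#' Generate synthetic centred sclerosed-glomerulus crops
#'
#' Emulates the centred crop/mask training pairs: each crop is a textured
#' pink background with one homogeneous dark ellipse centred at
#' `(size/2, size/2)` and the matching binary mask.
#'
#' @param n number of crops (>= 1).
#' @param size crop side length (default 256).
#' @param seed integer RNG seed.
#' @param radius_range min/max ellipse semi-axes in pixels (default scaled
#'   to a quarter of the crop).
#' @return list of [GlomCrop-class] objects.
#' @export
makeFixtureCrops <- function(n, size = 256L, seed = 1L, radius_range = NULL) {
  stopifnot(n >= 1)
  size <- as.integer(size)
  if (is.null(radius_range)) radius_range <- c(0.18, 0.32) * size
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      img <- array(0, dim = c(size, size, 3))
      for (c in 1:3)
        img[, , c] <- PAS_PINK[c] + 0.05 * smoothNoise(size, size) +
          stats::rnorm(size * size, 0, 0.015)
      a <- stats::runif(1, radius_range[1], radius_range[2])
      b <- stats::runif(1, radius_range[1], radius_range[2])
      th <- stats::runif(1, 0, pi)
      cx <- size / 2; cy <- size / 2
      poly <- ellipsePolygon(cx, cy, a, b, th)
      fill <- cpp_fill_polygon(size, size, poly[, 1], poly[, 2])
      img <- paintGlom(img, fill, "sclerosed")
      img[img < 0] <- 0; img[img > 1] <- 1
      mask <- fill
      storage.mode(mask) <- "double"
      new("GlomCrop", image = img, mask = mask, centre = c(cx, cy),
          radius = max(a, b), truncated = FALSE)
    })
  })
}
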