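## Slide preprocessing: downsampling, annotation rasterization, overlapped
## tiling and centred sclerosed-glomerulus crops.

blockMean2D <- function(x, f) {
  H <- nrow(x) %/% f * f
  W <- ncol(x) %/% f * f
  y <- array(x[seq_len(H), seq_len(W)], dim = c(f, H %/% f, f, W %/% f))
  m1 <- colMeans(y)                       # (H/f, f, W/f)
  colMeans(aperm(m1, c(2, 1, 3)))         # (H/f, W/f)
}

#' Downsample a slide and its annotations
#'
#' Area-interpolated (block mean) downsampling by an integer factor; polygon
#' coordinates are divided by the same factor. The pipeline default of
#' factor 2 halves slides before tiling.
#'
#' @param slide an [AnnotatedSlide-class].
#' @param factor positive integer scale divisor.
#' @return A downsampled [AnnotatedSlide-class].
#' @export
downsampleSlide <- function(slide, factor = 2L) {
  stopifnot(is(slide, "AnnotatedSlide"))
  factor <- as.integer(factor)
  d <- dim(slide@image)
  if (factor < 1) stop("factor must be >= 1")
  if (factor > d[1] || factor > d[2])
    stop("factor larger than a slide dimension")
  if (factor == 1L) return(slide)
  img <- slide@image
  out <- array(0, dim = c(d[1] %/% factor, d[2] %/% factor, 3))
  for (c in 1:3) out[, , c] <- blockMean2D(img[, , c], factor)
  out[out < 0] <- 0; out[out > 1] <- 1
  anns <- lapply(slide@annotations, function(a)
    list(polygon = a$polygon / factor, label = a$label))
  AnnotatedSlide(out, anns)
}

#' Rasterize polygon annotations into per-class binary masks
#'
#' Fills each polygon interior (even-odd rule, boundary pixels included) and
#' unions same-class polygons. Degenerate polygons (< 3 distinct vertices)
#' are skipped with a warning. A pixel claimed by both classes is assigned to
#' the sclerosed mask (with a warning).
#'
#' @param slide an [AnnotatedSlide-class].
#' @return `list(maskNormal, maskSclerosed)` of `H x W` 0/1 matrices.
#' @export
rasterizeAnnotations <- function(slide) {
  stopifnot(is(slide, "AnnotatedSlide"))
  d <- dim(slide@image)
  masks <- list(normal = matrix(0, d[1], d[2]),
                sclerosed = matrix(0, d[1], d[2]))
  for (a in slide@annotations) {
    p <- unique(a$polygon)
    if (nrow(p) < 3) {
      warning("skipping degenerate polygon (<3 distinct vertices)")
      next
    }
    fill <- cpp_fill_polygon(d[1], d[2], a$polygon[, 1], a$polygon[, 2])
    masks[[a$label]] <- pmax(masks[[a$label]], fill)
  }
  overlap <- masks$normal * masks$sclerosed
  if (any(overlap > 0)) {
    warning(sprintf("%d pixels claimed by both classes assigned to sclerosed",
                    sum(overlap)))
    masks$normal <- masks$normal * (1 - masks$sclerosed)
  }
  list(maskNormal = masks$normal, maskSclerosed = masks$sclerosed)
}

axisStarts <- function(n, window, stride) {
  if (n <= window) return(0L)
  st <- seq.int(0L, n - window, by = stride)
  if (st[length(st)] + window < n) st <- c(st, n - window)
  unique(as.integer(st))
}

reflectPadTo <- function(x, H, W) {
  idx <- function(n, m) {
    i <- seq_len(m) - 1L
    p <- i %% (2L * n - 2L)
    ifelse(p < n, p, 2L * n - 2L - p) + 1L
  }
  if (is.matrix(x)) return(x[idx(nrow(x), H), idx(ncol(x), W)])
  x[idx(dim(x)[1], H), idx(dim(x)[2], W), , drop = FALSE]
}

#' Cut a raster and its class masks into overlapping tiles
#'
#' Window origins run over `{0, stride, 2*stride, ...}` per axis; a final
#' window that would overshoot is shifted flush with the image edge so every
#' pixel is covered. Images smaller than the window are reflect-padded to a
#' single tile.
#'
#' @param image numeric array `c(H, W, 3)`.
#' @param maskNormal,maskSclerosed optional `H x W` 0/1 matrices (default
#'   all-zero).
#' @param window tile side length (default 1024).
#' @param stride step between window origins (default 512).
#' @return List of [Tile-class] objects, origins `(x, y)`.
#' @export
tileWithOverlap <- function(image, maskNormal = NULL, maskSclerosed = NULL,
                            window = 1024L, stride = 512L) {
  window <- as.integer(window); stride <- as.integer(stride)
  stopifnot(stride >= 1L)
  d <- dim(image)
  if (is.null(maskNormal)) maskNormal <- matrix(0, d[1], d[2])
  if (is.null(maskSclerosed)) maskSclerosed <- matrix(0, d[1], d[2])
  if (d[1] < window || d[2] < window) {
    H <- max(d[1], window); W <- max(d[2], window)
    image <- reflectPadTo(image, H, W)
    maskNormal <- reflectPadTo(maskNormal, H, W)
    maskSclerosed <- reflectPadTo(maskSclerosed, H, W)
    d <- dim(image)
  }
  xs <- axisStarts(d[2], window, stride)
  ys <- axisStarts(d[1], window, stride)
  tiles <- vector("list", length(xs) * length(ys))
  i <- 0L
  for (y0 in ys) for (x0 in xs) {
    i <- i + 1L
    ry <- (y0 + 1L):(y0 + window)
    rx <- (x0 + 1L):(x0 + window)
    tiles[[i]] <- new("Tile",
                      image = image[ry, rx, , drop = FALSE],
                      maskNormal = maskNormal[ry, rx],
                      maskSclerosed = maskSclerosed[ry, rx],
                      origin = c(x0, y0))
  }
  tiles
}

## ---- minimum enclosing circle (Welzl) -------------------------------------

circleFrom2 <- function(a, b) {
  c0 <- (a + b) / 2
  list(centre = c0, radius = sqrt(sum((a - c0)^2)))
}

circleFrom3 <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(dd) < 1e-12) return(NULL) # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
  ctr <- c(ux, uy)
  list(centre = ctr, radius = sqrt(sum((a - ctr)^2)))
}

inCircle <- function(p, circ, tol = 1e-7) {
  sqrt(sum((p - circ$centre)^2)) <= circ$radius + tol
}

trivialCircle <- function(R) {
  n <- nrow(R)
  if (n == 0) return(list(centre = c(0, 0), radius = 0))
  if (n == 1) return(list(centre = R[1, ], radius = 0))
  if (n == 2) return(circleFrom2(R[1, ], R[2, ]))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    c2 <- circleFrom2(R[pair[1], ], R[pair[2], ])
    if (all(vapply(1:3, function(i) inCircle(R[i, ], c2), logical(1))))
      return(c2)
  }
  c3 <- circleFrom3(R[1, ], R[2, ], R[3, ])
  if (is.null(c3)) circleFrom2(R[which.min(R[, 1]), ], R[which.max(R[, 1]), ])
  else c3
}

welzl <- function(P, R) {
  if (nrow(P) == 0 || nrow(R) == 3) return(trivialCircle(R))
  p <- P[nrow(P), ]
  D <- welzl(P[-nrow(P), , drop = FALSE], R)
  if (inCircle(p, D)) return(D)
  welzl(P[-nrow(P), , drop = FALSE], rbind(R, p))
}

#' Minimum enclosing circle of a 2-D point set
#'
#' Exact smallest circle containing all points (Welzl's algorithm; the input
#' order is permuted deterministically for balance).
#'
#' @param points `n x 2` matrix of `(x, y)` coordinates.
#' @return `list(centre = c(x, y), radius = r)`.
#' @export
minEnclosingCircle <- function(points) {
  points <- unique(matrix(as.numeric(points), ncol = 2,
                          dimnames = NULL))
  if (nrow(points) == 0) stop("empty point set")
  ## deterministic shuffle keeps expected-linear behaviour without RNG state
  ord <- order((seq_len(nrow(points)) * 2654435761) %% 4294967296)
  welzl(points[ord, , drop = FALSE], matrix(numeric(0), 0, 2))
}

#' Extract a centred crop of one sclerosed glomerulus
#'
#' Computes the minimum enclosing circle of the polygon vertices, centres a
#' `crop x crop` box on the (rounded) circle centre, translates the box
#' inward where it would cross the slide border (never pads), and returns
#' the image crop plus the binary mask of the polygon interior within the
#' crop. Glomeruli wider than the crop are returned with `truncated = TRUE`.
#'
#' @param slide an [AnnotatedSlide-class].
#' @param polygon `n x 2` vertex matrix, or the index of a sclerosed
#'   annotation in `annotations(slide)`.
#' @param crop crop side length (default 256).
#' @return A [GlomCrop-class].
#' @export
extractGlomCrop <- function(slide, polygon, crop = 256L) {
  stopifnot(is(slide, "AnnotatedSlide"))
  crop <- as.integer(crop)
  if (length(polygon) == 1 && is.numeric(polygon))
    polygon <- slide@annotations[[polygon]]$polygon
  d <- dim(slide@image)
  if (d[1] < crop || d[2] < crop) stop("slide smaller than the crop window")
  mec <- minEnclosingCircle(polygon)
  cx <- round(mec$centre[1]); cy <- round(mec$centre[2])
  x0 <- max(0L, min(as.integer(cx) - crop %/% 2L, d[2] - crop))
  y0 <- max(0L, min(as.integer(cy) - crop %/% 2L, d[1] - crop))
  fill <- cpp_fill_polygon(d[1], d[2], polygon[, 1], polygon[, 2])
  ry <- (y0 + 1L):(y0 + crop)
  rx <- (x0 + 1L):(x0 + crop)
  mask <- fill[ry, rx]
  storage.mode(mask) <- "double"
  new("GlomCrop",
      image = slide@image[ry, rx, , drop = FALSE],
      mask = mask,
      centre = mec$centre,
      radius = mec$radius,
      truncated = 2 * mec$radius > crop)
}
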