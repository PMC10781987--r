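## Test-phase synthesis: pick tissue positions in a region of interest,
## blank a generated mask there, inpaint with the trained generator, paste
## the composite back, and update the annotations.

saturationMatrix <- function(image) {
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  mn <- pmin(image[, , 1], image[, , 2], image[, , 3])
  s <- (mx - mn) / mx
  s[mx == 0] <- 0
  s
}

integralImage <- function(m) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)
  t(ii)
}

boxSum <- function(ii, y0, x0, w) {
  ## sum over rows (y0+1):(y0+w), cols (x0+1):(x0+w) using the integral image
  a <- ii[y0 + w, x0 + w]
  b <- if (y0 > 0) ii[y0, x0 + w] else 0
  cc <- if (x0 > 0) ii[y0 + w, x0] else 0
  d <- if (y0 > 0 && x0 > 0) ii[y0, x0] else 0
  a - b - cc + d
}

#' Propose crop positions for synthetic glomeruli in a region of interest
#'
#' Samples non-overlapping `crop x crop` windows that lie in tissue (mean
#' HSV saturation within the window above `satThreshold`) and avoid every
#' existing glomerulus annotation. Deterministic under `seed`; if fewer
#' than `n` valid windows are found a warning is raised and the found
#' subset returned.
#'
#' @param roi an [AnnotatedSlide-class].
#' @param n number of positions requested.
#' @param seed RNG seed.
#' @param crop window size (default 256).
#' @param satThreshold tissue saturation threshold (default 0.15).
#' @param maxTries sampling budget.
#' @return list of integer `c(x, y)` window origins.
#' @export
proposePositions <- function(roi, n, seed = 1L, crop = 256L,
                             satThreshold = 0.15, maxTries = 2000L) {
  stopifnot(is(roi, "AnnotatedSlide"))
  d <- dim(roi@image)
  if (d[1] < crop || d[2] < crop) stop("roi smaller than the crop window")
  if (n == 0) return(list())
  sat <- saturationMatrix(roi@image)
  iiSat <- integralImage(sat)
  masks <- rasterizeAnnotations(roi)
  occupied <- pmax(masks$maskNormal, masks$maskSclerosed)
  iiOcc <- integralImage(occupied)
  taken <- matrix(0, d[1], d[2])
  iiTakenStale <- TRUE
  found <- list()
  withSeed(seed, {
    tries <- 0L
    while (length(found) < n && tries < maxTries) {
      tries <- tries + 1L
      x0 <- sample.int(d[2] - crop + 1L, 1L) - 1L
      y0 <- sample.int(d[1] - crop + 1L, 1L) - 1L
      if (boxSum(iiSat, y0, x0, crop) / crop^2 <= satThreshold) next
      if (boxSum(iiOcc, y0, x0, crop) > 0) next
      ## overlap with already accepted windows
      clash <- FALSE
      for (p in found)
        if (abs(p[1] - x0) < crop && abs(p[2] - y0) < crop) {
          clash <- TRUE
          break
        }
      if (clash) next
      found[[length(found) + 1L]] <- c(x = x0, y = y0)
    }
  })
  if (length(found) < n)
    warning(sprintf("found only %d of %d requested positions",
                    length(found), n))
  found
}

## trace the outer boundary of a binary component as a pixel-edge polygon
## (vertices on half-integer coordinates, foreground on the left)
traceBoundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  fg <- function(y, x) y >= 1 && y <= H && x >= 1 && x <= W && mask[y, x] > 0
  ## collect directed edges along pixel borders, keyed by start vertex
  ## a vertex can start two edges at diagonal pixel contacts, so store lists
  edges <- new.env(parent = emptyenv())
  addEdge <- function(from, to) {
    k <- paste(from, collapse = ",")
    edges[[k]] <- c(edges[[k]], list(list(from = from, to = to)))
  }
  for (y in seq_len(H)) for (x in seq_len(W)) {
    if (mask[y, x] == 0) next
    ## vertices in 0-based pixel-centred coords; pixel (x-1, y-1) spans
    ## [x-1.5, x-0.5] etc. Directed so interior stays on the left.
    if (!fg(y - 1, x)) addEdge(c(x - 1.5, y - 1.5), c(x - 0.5, y - 1.5))
    if (!fg(y + 1, x)) addEdge(c(x - 0.5, y - 0.5), c(x - 1.5, y - 0.5))
    if (!fg(y, x - 1)) addEdge(c(x - 1.5, y - 0.5), c(x - 1.5, y - 1.5))
    if (!fg(y, x + 1)) addEdge(c(x - 0.5, y - 1.5), c(x - 0.5, y - 0.5))
  }
  keys <- ls(edges)
  if (length(keys) == 0) return(NULL)
  ## walk loops, consuming edges; return the longest (outer boundary)
  bestLoop <- NULL
  for (k in keys) {
    repeat {
      if (length(edges[[k]] %||% list()) == 0) break
      loop <- list()
      cur <- k
      repeat {
        es <- edges[[cur]]
        if (is.null(es) || length(es) == 0) break
        e <- es[[1]]
        edges[[cur]] <- es[-1]
        loop[[length(loop) + 1L]] <- e$from
        cur <- paste(e$to, collapse = ",")
        if (cur == k && length(edges[[k]] %||% list()) == 0) break
        if (cur == k) break
      }
      if (is.null(bestLoop) || length(loop) > length(bestLoop))
        bestLoop <- loop
    }
  }
  do.call(rbind, bestLoop)
}

#' Convert a binary mask to polygon annotations
#'
#' Traces the outer pixel-edge boundary of each 8-connected component;
#' rasterizing the returned polygons (even-odd, boundary included)
#' reproduces the component supports to within one pixel at the border.
#'
#' @param mask binary `H x W` matrix.
#' @param label class label attached to each polygon.
#' @param offset `c(x, y)` added to all coordinates (for crops pasted into
#'   a larger raster).
#' @return list of `list(polygon, label)` records.
#' @export
maskToAnnotations <- function(mask, label = "sclerosed", offset = c(0, 0)) {
  bin <- mask > 0.5
  storage.mode(bin) <- "integer"
  lab <- cpp_label_components(bin, 8L)
  out <- list()
  for (cc in seq_len(max(lab, 0))) {
    poly <- traceBoundary((lab == cc) * 1)
    if (is.null(poly) || nrow(poly) < 3) next
    poly[, 1] <- poly[, 1] + offset[1]
    poly[, 2] <- poly[, 2] + offset[2]
    out[[length(out) + 1L]] <- list(polygon = poly, label = label)
  }
  out
}

#' Synthesize sclerosed glomeruli into a region of interest
#'
#' For each position: crop the 256x256 window, blank the assigned generated
#' mask (`Xgap = Xori * (1 - Xgmask)`), run the inpainting generator on the
#' gap/mask stack, composite `Xrec` inside the mask with the original
#' pixels outside, paste the window back and append one sclerosed polygon
#' annotation per mask component. Pixels outside all masks are bitwise
#' unchanged.
#'
#' @param roi an [AnnotatedSlide-class].
#' @param masks list of [MaskArtifact-class] (at least one per position).
#' @param generator trained generator model, or a function
#'   `(InpaintSample) -> Xrec` (identity oracle: `function(s) s@Xori`).
#' @param positions list of `c(x, y)` origins from [proposePositions()].
#' @param seed seed for the random mask-to-position assignment.
#' @return augmented [AnnotatedSlide-class].
#' @export
synthesizeROI <- function(roi, masks, generator, positions, seed = 1L) {
  stopifnot(is(roi, "AnnotatedSlide"))
  if (length(positions) == 0) return(roi)
  if (length(masks) < length(positions))
    stop("need at least one mask per position")
  d <- dim(roi@image)
  crop <- nrow(maskRaster(masks[[1]]))
  img <- roi@image
  anns <- roi@annotations
  perm <- withSeed(seed, sample.int(length(masks)))
  for (i in seq_along(positions)) {
    p <- positions[[i]]
    x0 <- as.integer(p[1]); y0 <- as.integer(p[2])
    if (x0 < 0 || y0 < 0 || x0 + crop > d[2] || y0 + crop > d[1])
      stop(sprintf("position (%d, %d) out of bounds", x0, y0))
    gm <- maskRaster(masks[[perm[i]]])
    ry <- (y0 + 1L):(y0 + crop); rx <- (x0 + 1L):(x0 + crop)
    Xori_t <- img[ry, rx, , drop = FALSE]
    sample <- makeInpaintInput(Xori_t, gm)
    Xrec <- runInpainter(generator, sample)
    m3 <- array(rep(gm, 3), dim = dim(Xori_t))
    Xout <- Xrec * m3 + Xori_t * (1 - m3)
    img[ry, rx, ] <- Xout
    anns <- c(anns, maskToAnnotations(gm, "sclerosed",
                                      offset = c(x0, y0)))
  }
  AnnotatedSlide(img, anns)
}

#' Mix original and synthesized tiles into a training manifest
#'
#' Includes every original tile plus `round(fraction * pool)` synthesized
#' tiles (fraction relative to the synthesized pool size), shuffled under
#' `seed`.
#'
#' @param originalTiles,synthTiles lists of [Tile-class] (or segmentation
#'   samples).
#' @param fraction synthesized fraction in `(0, 1]` (the reported settings
#'   are 0.3, 0.6 and 1.0).
#' @param seed RNG seed.
#' @return `list(tiles, manifest)`: the mixed list and a data frame with
#'   columns `source` / `index` in emission order.
#' @export
emitTrainingSet <- function(originalTiles, synthTiles, fraction, seed = 1L) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  nTake <- round(fraction * length(synthTiles))
  if (length(synthTiles) < nTake || length(synthTiles) == 0)
    stop(sprintf("synthesized pool too small: need %d tiles", max(nTake, 1)))
  withSeed(seed, {
    take <- sample.int(length(synthTiles), nTake)
    man <- rbind(
      data.frame(source = "original",
                 index = seq_along(originalTiles)),
      data.frame(source = "synthetic", index = take))
    man <- man[sample.int(nrow(man)), , drop = FALSE]
    rownames(man) <- NULL
    tiles <- lapply(seq_len(nrow(man)), function(i)
      if (man$source[i] == "original") originalTiles[[man$index[i]]]
      else synthTiles[[man$index[i]]])
    list(tiles = tiles, manifest = man)
  })
}
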