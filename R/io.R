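## File formats: 8-bit RGB PNG rasters, 0/255 PNG masks, GeoJSON
## FeatureCollection annotations and tab-separated manifests.

#' Read an RGB raster from PNG
#' @param path PNG file (8- or 16-bit; grayscale is expanded to RGB, alpha
#'   dropped).
#' @return numeric array `c(H, W, 3)` in `[0, 1]`.
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), dim = c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  x
}

#' Write an RGB raster to PNG
#' @param image numeric array `c(H, W, 3)` in `[0, 1]`.
#' @param path output file.
#' @export
writeImagePNG <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a binary mask from PNG (0/255 convention)
#' @param path PNG file; any channel value > 0.5 counts as foreground.
#' @return numeric `H x W` matrix in `{0, 1}`.
#' @export
readMaskPNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  (x > 0.5) * 1
}

#' Write a binary mask to PNG (0/255 convention)
#' @param mask numeric `H x W` matrix in `{0, 1}`.
#' @param path output file.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG((mask > 0.5) * 1, path)
  invisible(path)
}

#' Read a YAML training configuration
#'
#' Sections (all optional): `model` (arguments to [buildGenerator()]),
#' `loss` (named overrides of [lossWeights()]: adv, l1g, l1l, per, sty),
#' `optim` (arguments to [inpaintTrainConfig()]), `seg` (arguments to
#' [segTrainConfig()]).
#'
#' @param path YAML file.
#' @return `list(model, weights, optim, seg)` ready to pass to the
#'   trainers.
#' @export
readTrainConfigYAML <- function(path) {
  y <- yaml::read_yaml(path)
  w <- lossWeights()
  for (nm in names(y$loss)) {
    if (!nm %in% names(w)) stop("unknown loss weight: ", nm)
    w[nm] <- y$loss[[nm]]
  }
  list(model = y$model %||% list(),
       weights = w,
       optim = do.call(inpaintTrainConfig, y$optim %||% list()),
       seg = do.call(segTrainConfig, y$seg %||% list()))
}

#' Read glomerulus annotations from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features with a `classification`
#' property equal to `"normal"` or `"sclerosed"`. Only the outer ring is
#' used; a closing vertex equal to the first is dropped.
#'
#' @param path GeoJSON file.
#' @return list of `list(polygon, label)` records.
#' @export
readAnnotationsGeoJSON <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection")
  lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported")
    ring <- f$geometry$coordinates[[1]]
    p <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    lab <- f$properties$classification
    if (!lab %in% GLOM_CLASSES) stop("classification must be normal/sclerosed")
    list(polygon = p, label = lab)
  })
}

#' Write glomerulus annotations to GeoJSON
#' @param annotations list of `list(polygon, label)` records.
#' @param path output file.
#' @export
writeAnnotationsGeoJSON <- function(annotations, path) {
  feats <- lapply(annotations, function(a) {
    ring <- rbind(a$polygon, a$polygon[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = list(classification = a$label))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotated slide (PNG raster + GeoJSON outlines)
#' @param imagePath PNG raster.
#' @param annotationPath GeoJSON FeatureCollection (optional).
#' @return An [AnnotatedSlide-class].
#' @export
readAnnotatedSlide <- function(imagePath, annotationPath = NULL) {
  anns <- if (is.null(annotationPath)) list()
          else readAnnotationsGeoJSON(annotationPath)
  AnnotatedSlide(readImagePNG(imagePath), anns)
}

#' Write tiles and their masks to a directory with a TSV manifest
#'
#' Emits `tile_<i>.png`, `tile_<i>_normal.png`, `tile_<i>_sclerosed.png`
#' (masks as 0/255) and `manifest.tsv` with columns tile, mask_normal,
#' mask_sclerosed, x, y.
#'
#' @param tiles list of [Tile-class] objects.
#' @param dir output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
writeTiles <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(tiles), function(i) {
    t <- tiles[[i]]
    base <- sprintf("tile_%04d", i)
    writeImagePNG(t@image, file.path(dir, paste0(base, ".png")))
    writeMaskPNG(t@maskNormal, file.path(dir, paste0(base, "_normal.png")))
    writeMaskPNG(t@maskSclerosed, file.path(dir, paste0(base, "_sclerosed.png")))
    data.frame(tile = paste0(base, ".png"),
               mask_normal = paste0(base, "_normal.png"),
               mask_sclerosed = paste0(base, "_sclerosed.png"),
               x = t@origin[1], y = t@origin[2])
  })
  man <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.tsv")
  utils::write.table(man, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tile manifest written by [writeTiles()]
#' @param path manifest.tsv path.
#' @return list of [Tile-class] objects.
#' @export
readTiles <- function(path) {
  dir <- dirname(path)
  man <- utils::read.delim(path)
  lapply(seq_len(nrow(man)), function(i) {
    new("Tile",
        image = readImagePNG(file.path(dir, man$tile[i])),
        maskNormal = readMaskPNG(file.path(dir, man$mask_normal[i])),
        maskSclerosed = readMaskPNG(file.path(dir, man$mask_sclerosed[i])),
        origin = c(as.integer(man$x[i]), as.integer(man$y[i])))
  })
}
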