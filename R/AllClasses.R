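## Central S4 data types.
##
## Raster conventions used throughout: images are numeric arrays
## dim c(H, W, 3) with values in [0, 1]; masks are numeric H x W matrices
## with values in {0, 1}. Pixel coordinates are 0-based and pixel-centred,
## x rightward (columns), y downward (rows); boxes are half-open.

GLOM_CLASSES <- c("normal", "sclerosed")

#' AnnotatedSlide: an RGB raster with class-labelled glomerulus outlines
#'
#' Holds a slide (or region-of-interest) raster together with polygon
#' annotations. Each annotation is a `list(polygon = <n x 2 matrix of (x, y)
#' vertices>, label = "normal"|"sclerosed")`. Vertices are clipped to the
#' raster bounds by the constructor.
#'
#' @slot image numeric array, dim `c(H, W, 3)`, values in `[0, 1]`.
#' @slot annotations list of annotation records (see above).
#' @export
setClass("AnnotatedSlide",
         representation(image = "array", annotations = "list"))

setValidity("AnnotatedSlide", function(object) {
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) return("image must be an H x W x 3 array")
  if (min(object@image) < 0 || max(object@image) > 1)
    return("image values must lie in [0, 1]")
  for (a in object@annotations) {
    if (!is.list(a) || is.null(a$polygon) || is.null(a$label))
      return("each annotation needs $polygon and $label")
    if (!a$label %in% GLOM_CLASSES)
      return(sprintf("label must be one of %s", paste(GLOM_CLASSES, collapse = "/")))
    p <- a$polygon
    if (!is.matrix(p) || ncol(p) != 2) return("polygon must be an n x 2 matrix")
    if (nrow(p) > 0 && (min(p[, 1]) < 0 || max(p[, 1]) >= d[2] ||
                        min(p[, 2]) < 0 || max(p[, 2]) >= d[1]))
      return("polygon vertices must lie within [0, W) x [0, H)")
  }
  TRUE
})

#' Construct an AnnotatedSlide
#'
#' @param image numeric array `c(H, W, 3)` in `[0, 1]`.
#' @param annotations list of `list(polygon, label)` records; vertices are
#'   clipped into `[0, W) x [0, H)`.
#' @return An [AnnotatedSlide-class] object.
#' @export
AnnotatedSlide <- function(image, annotations = list()) {
  d <- dim(image)
  anns <- lapply(annotations, function(a) {
    p <- a$polygon
    storage.mode(p) <- "double"
    p[, 1] <- pmin(pmax(p[, 1], 0), d[2] - 1)
    p[, 2] <- pmin(pmax(p[, 2], 0), d[1] - 1)
    list(polygon = p, label = a$label)
  })
  new("AnnotatedSlide", image = image, annotations = anns)
}

#' Tile: a fixed-size training window with per-class masks
#'
#' @slot image numeric array `c(w, w, 3)`.
#' @slot maskNormal,maskSclerosed numeric `w x w` matrices in `{0, 1}`;
#'   the two class masks never overlap.
#' @slot origin integer `(x, y)` offset of the tile in its source raster.
#' @export
setClass("Tile",
         representation(image = "array", maskNormal = "matrix",
                        maskSclerosed = "matrix", origin = "integer"))

setValidity("Tile", function(object) {
  if (!all(object@maskNormal %in% c(0, 1)) ||
      !all(object@maskSclerosed %in% c(0, 1)))
    return("mask values must be 0/1")
  if (any(object@maskNormal * object@maskSclerosed > 0))
    return("class masks may not overlap")
  if (length(object@origin) != 2) return("origin must be length-2 (x, y)")
  TRUE
})

#' GlomCrop: a centred crop of one sclerosed glomerulus
#'
#' The crop is centred on the centre of the minimum enclosing circle of the
#' glomerulus outline (translated inward at slide borders) and carries the
#' binary mask of the outline interior within the crop.
#'
#' @slot image numeric array `c(s, s, 3)` (X_ori).
#' @slot mask numeric `s x s` matrix in `{0, 1}` (X_mask).
#' @slot centre numeric `(x, y)` circle centre in slide coordinates.
#' @slot radius numeric; minimum enclosing circle radius (pixels).
#' @slot truncated logical; TRUE when the circle diameter exceeds the crop.
#' @export
setClass("GlomCrop",
         representation(image = "array", mask = "matrix", centre = "numeric",
                        radius = "numeric", truncated = "logical"))

setValidity("GlomCrop", function(object) {
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) return("image must be H x W x 3")
  if (!all(dim(object@mask) == d[1:2])) return("mask/image shape mismatch")
  if (!all(object@mask %in% c(0, 1))) return("mask values must be 0/1")
  TRUE
})

#' MaskArtifact: a synthesized binary glomerulus mask with provenance
#'
#' @slot raster numeric `H x W` matrix in `{0, 1}`.
#' @slot provenance one of `"real"`, `"sampled"`, `"postprocessed"`,
#'   `"scaled"`.
#' @slot scaleFactor numeric; cumulative contour scale factor (1 if unscaled).
#' @export
setClass("MaskArtifact",
         representation(raster = "matrix", provenance = "character",
                        scaleFactor = "numeric"))

setValidity("MaskArtifact", function(object) {
  if (!all(object@raster %in% c(0, 1))) return("raster values must be 0/1")
  if (!object@provenance %in% c("real", "sampled", "postprocessed", "scaled"))
    return("unknown provenance")
  if (object@scaleFactor <= 0) return("scaleFactor must be positive")
  TRUE
})

#' Construct a MaskArtifact
#' @param raster binary `H x W` matrix.
#' @param provenance provenance tag.
#' @param scaleFactor cumulative scale factor.
#' @return A [MaskArtifact-class] object.
#' @export
MaskArtifact <- function(raster, provenance = "real", scaleFactor = 1) {
  storage.mode(raster) <- "double"
  new("MaskArtifact", raster = raster, provenance = provenance,
      scaleFactor = scaleFactor)
}

#' InpaintSample: the model input tuple for one glomerulus crop
#'
#' `Xgap = Xori * (1 - Xmask)` (background only, glomerulus blanked) and
#' `Xinput` is the channelwise concatenation of `Xgap` and `Xmask`.
#'
#' @slot Xori numeric array `c(s, s, 3)` in `[0, 1]`.
#' @slot Xmask numeric `s x s` matrix in `{0, 1}` (1 = glomerulus).
#' @slot Xgap numeric array `c(s, s, 3)`.
#' @slot Xinput numeric array `c(s, s, 4)`.
#' @export
setClass("InpaintSample",
         representation(Xori = "array", Xmask = "matrix", Xgap = "array",
                        Xinput = "array"))

setValidity("InpaintSample", function(object) {
  d <- dim(object@Xori)
  if (!all(dim(object@Xmask) == d[1:2])) return("Xmask/Xori shape mismatch")
  if (!all(object@Xmask %in% c(0, 1))) return("Xmask must be binary")
  m3 <- array(rep(object@Xmask, 3), dim = dim(object@Xgap))
  if (any(abs(object@Xgap * m3) > 0))
    return("Xgap must be zero wherever Xmask = 1")
  if (!all(dim(object@Xinput) == c(d[1], d[2], 4)))
    return("Xinput must have 4 channels")
  TRUE
})

#' LossReport: all inpainting loss components for one batch
#'
#' @slot advg,advl adversarial scores (global/local discriminator terms
#'   entering the generator objective).
#' @slot l1g,l1l global/local mean-absolute pixel reconstruction losses.
#' @slot per,sty perceptual and style losses.
#' @slot total weighted total.
#' @slot perLayer list of per-feature-layer contributions to per/sty.
#' @slot weights numeric vector of the weights used.
#' @export
setClass("LossReport",
         representation(advg = "numeric", advl = "numeric", l1g = "numeric",
                        l1l = "numeric", per = "numeric", sty = "numeric",
                        total = "numeric", perLayer = "list",
                        weights = "numeric"))

## ---- show methods ---------------------------------------------------------

setMethod("show", "AnnotatedSlide", function(object) {
  d <- dim(object@image)
  labs <- vapply(object@annotations, function(a) a$label, character(1))
  cat(sprintf("AnnotatedSlide %d x %d with %d annotations (%d normal, %d sclerosed)\n",
              d[2], d[1], length(labs), sum(labs == "normal"),
              sum(labs == "sclerosed")))
})

setMethod("show", "Tile", function(object) {
  cat(sprintf("Tile %dpx at (%d, %d): %d normal / %d sclerosed mask px\n",
              nrow(object@maskNormal), object@origin[1], object@origin[2],
              sum(object@maskNormal), sum(object@maskSclerosed)))
})

setMethod("show", "GlomCrop", function(object) {
  cat(sprintf("GlomCrop %dpx centred at (%.1f, %.1f), r = %.1f%s, %d mask px\n",
              nrow(object@mask), object@centre[1], object@centre[2],
              object@radius, if (object@truncated) " (truncated)" else "",
              sum(object@mask)))
})

setMethod("show", "MaskArtifact", function(object) {
  cat(sprintf("MaskArtifact %dx%d [%s] scale %.2f, %d foreground px\n",
              ncol(object@raster), nrow(object@raster), object@provenance,
              object@scaleFactor, sum(object@raster)))
})

setMethod("show", "InpaintSample", function(object) {
  cat(sprintf("InpaintSample %dpx, %d masked px\n", nrow(object@Xmask),
              sum(object@Xmask)))
})

setMethod("show", "LossReport", function(object) {
  cat(sprintf(paste0("LossReport: total %.4f (advg %.4f advl %.4f l1g %.4f ",
                     "l1l %.4f per %.4f sty %.4f)\n"),
              object@total, object@advg, object@advl, object@l1g,
              object@l1l, object@per, object@sty))
})
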