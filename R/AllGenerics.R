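## Accessor generics for the S4 data types.

#' Accessors for glomopaint data objects
#'
#' Small accessor family: `slideImage()` and `annotations()` read the raster
#' and the polygon annotations of an [AnnotatedSlide-class]; `cropImage()`
#' and `cropMask()` read a [GlomCrop-class]; `maskRaster()`, `provenance()`
#' and `scaleFactor()` read a [MaskArtifact-class]; `tileOrigin()` reads a
#' [Tile-class] offset.
#'
#' @param x the object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("slideImage", function(x) standardGeneric("slideImage"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("cropImage", function(x) standardGeneric("cropImage"))
#' @rdname accessors
#' @export
setGeneric("cropMask", function(x) standardGeneric("cropMask"))
#' @rdname accessors
#' @export
setGeneric("maskRaster", function(x) standardGeneric("maskRaster"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("scaleFactor", function(x) standardGeneric("scaleFactor"))
#' @rdname accessors
#' @export
setGeneric("tileOrigin", function(x) standardGeneric("tileOrigin"))

#' @rdname accessors
#' @export
setMethod("slideImage", "AnnotatedSlide", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("annotations", "AnnotatedSlide", function(x) x@annotations)
#' @rdname accessors
#' @export
setMethod("cropImage", "GlomCrop", function(x) x@image)
#' @rdname accessors
#' @export
setMethod("cropMask", "GlomCrop", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("maskRaster", "MaskArtifact", function(x) x@raster)
#' @rdname accessors
#' @export
setMethod("provenance", "MaskArtifact", function(x) x@provenance)
#' @rdname accessors
#' @export
setMethod("scaleFactor", "MaskArtifact", function(x) x@scaleFactor)
#' @rdname accessors
#' @export
setMethod("tileOrigin", "Tile", function(x) x@origin)
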