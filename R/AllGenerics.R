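#' @include AllClasses.R
NULL

#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param object an S4 object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("entropyValues", function(object) standardGeneric("entropyValues"))

#' @rdname accessors
#' @export
setMethod("entropyValues", "EntropyMap", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("kernelSize", function(object) standardGeneric("kernelSize"))

#' @rdname accessors
#' @export
setMethod("kernelSize", "EntropyMap",
  function(object) c(z = object@kernelZ, x = object@kernelX))

#' @rdname accessors
#' @export
setGeneric("jonesArray", function(object) standardGeneric("jonesArray"))

#' @rdname accessors
#' @export
setMethod("jonesArray", "JonesVolume", function(object) object@jones)

#' @rdname accessors
#' @export
setGeneric("binCenters", function(object) standardGeneric("binCenters"))

#' @rdname accessors
#' @export
setMethod("binCenters", "SectionProfile", function(object) object@binCenterMm)

#' @rdname accessors
#' @export
setGeneric("profileMeans", function(object) standardGeneric("profileMeans"))

#' @rdname accessors
#' @export
setMethod("profileMeans", "SectionProfile", function(object) object@meanValue)

#' @rdname accessors
#' @export
setGeneric("binCounts", function(object) standardGeneric("binCounts"))

#' @rdname accessors
#' @export
setMethod("binCounts", "SectionProfile", function(object) object@nPixels)

#' @rdname accessors
#' @export
setGeneric("isOriented", function(object) standardGeneric("isOriented"))

#' @rdname accessors
#' @export
setMethod("isOriented", "SectionProfile", function(object) object@oriented)

#' @rdname accessors
#' @export
setGeneric("melaninProfile", function(object) standardGeneric("melaninProfile"))

#' @rdname accessors
#' @export
setMethod("melaninProfile", "RetinalPhantom", function(object) object@melanin)

#' Ground-truth segmentation traces of a phantom
#'
#' Returns the synthetic-truth [SegTrace-class] for a phantom boundary.  The
#' "RPE" trace runs along the center of the depolarizing band (the line a
#' grader would draw), the "ILM" trace along the inner limiting membrane,
#' and "RPE-inner" along the inner RPE boundary used for central retinal
#' thickness.
#'
#' @param object a [RetinalPhantom-class].
#' @param boundary one of "RPE", "ILM", "RPE-inner".
#' @return A [SegTrace-class].
#' @export
setGeneric("truthTrace",
  function(object, boundary = c("RPE", "ILM", "RPE-inner"))
    standardGeneric("truthTrace"))

#' @rdname truthTrace
#' @export
setMethod("truthTrace", "RetinalPhantom", function(object, boundary) {
  boundary <- match.arg(boundary, c("RPE", "ILM", "RPE-inner"))
  cols <- seq_len(object@nCols)
  z <- switch(boundary,
    "RPE" = object@rpeZ + floor(object@rpeBandPx / 2) - 1,
    "ILM" = object@ilmZ,
    "RPE-inner" = object@rpeZ)
  b <- if (boundary == "ILM") "ILM" else "RPE"
  SegTrace(cols, z, boundary = b, source = "synthetic-truth")
})

setMethod("show", "RetinalPhantom", function(object) {
  cat(sprintf(
    "RetinalPhantom: %d cols x %d rows x %d B-scans (%.1f mm, %s)\n",
    object@nCols, object@nRows, object@nBscans, object@widthMm, object@eye))
  cat(sprintf("  fovea at column %d; melanin m in [%.3f, %.3f]\n",
    object@foveaCol, min(object@melanin), max(object@melanin)))
  cat(sprintf("  EZ half-width %.0f um; pixel %.2f x %.2f um\n",
    object@ezHalfwidthUm, object@pixelDxUm, object@pixelDzUm))
})

setMethod("show", "JonesVolume", function(object) {
  d <- dim(object@jones)
  cat(sprintf("JonesVolume: %d x %d pixels x %d B-scans (%s)\n",
    d[1], d[2], d[4], object@eye))
})

setMethod("show", "EntropyMap", function(object) {
  v <- object@values
  cat(sprintf("EntropyMap: %d x %d, kernel %d x %d, range [%.3f, %.3f]\n",
    nrow(v), ncol(v), object@kernelZ, object@kernelX,
    min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "SectionProfile", function(object) {
  cat(sprintf("%s: %d sections (%.2f mm wide), eye %s, %s\n",
    class(object), length(object@binCenterMm), object@binWidthMm,
    object@eye, if (object@oriented) "oriented" else "unoriented"))
})

setMethod("show", "AffineTransform2D", function(object) {
  cat("AffineTransform2D (A | b):\n")
  m <- cbind(object@A, object@b)
  rownames(m) <- c("x", "y"); colnames(m) <- c("a1", "a2", "b")
  print(round(m, 4))
  cat(sprintf("  RMS landmark residual: %.3f px\n", object@rmsResidual))
})

setMethod("show", "AFScene", function(object) {
  cat(sprintf("AFScene (%s): %d x %d image, %d landmarks\n",
    object@modality, nrow(object@image), ncol(object@image),
    nrow(object@landmarks)))
})
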