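#' @import methods
NULL

#' Acquisition noise specification
#'
#' Describes the stochastic components of a simulated PS-OCT acquisition:
#' the per-pixel signal-to-additive-noise ratio in dB (relative to the mean
#' RPE signal power, summed over the four Jones elements), whether fully
#' developed speckle modulates the signal amplitude, and the random seed
#' that makes the rendering bit-reproducible.
#'
#' @slot snrDb numeric(1), signal-to-noise ratio in dB; `Inf` disables
#'   additive noise.
#' @slot speckle logical(1), Rayleigh speckle amplitude on/off.
#' @slot seed integer(1), random seed for rendering.
#' @export
setClass("NoiseSpec",
  representation(snrDb = "numeric", speckle = "logical", seed = "integer"),
  prototype(snrDb = 25, speckle = TRUE, seed = 1L))

setValidity("NoiseSpec", function(object) {
  if (length(object@snrDb) != 1L || is.na(object@snrDb))
    return("snrDb must be a single finite value or Inf")
  if (length(object@speckle) != 1L || is.na(object@speckle))
    return("speckle must be TRUE or FALSE")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed must be a single integer")
  TRUE
})

#' Construct a NoiseSpec
#'
#' @param snrDb signal-to-noise ratio in dB (default 25; `Inf` = noise-free).
#' @param speckle enable Rayleigh speckle amplitudes (default `TRUE`).
#' @param seed integer random seed (default 1).
#' @return A [NoiseSpec-class] object.
#' @examples
#' NoiseSpec(snrDb = 20, speckle = FALSE, seed = 7)
#' @export
NoiseSpec <- function(snrDb = 25, speckle = TRUE, seed = 1L) {
  new("NoiseSpec", snrDb = as.numeric(snrDb), speckle = as.logical(speckle),
      seed = as.integer(seed))
}

#' Synthetic retinal phantom
#'
#' Geometric and optical ground truth for one simulated eye: boundary depth
#' profiles for the inner limiting membrane (ILM) and the RPE, the melanin
#' mixture-depolarization parameter along the RPE, the short-wavelength
#' fluorophore (lipofuscin) density, the macular-pigment attenuation factor,
#' the extent of the intact ellipsoid zone (EZ), and the scan geometry.
#' All per-column profiles are indexed 1..`nCols` (1-based, matching R).
#'
#' @slot nCols integer, A-scans per B-scan.
#' @slot nRows integer, depth pixels.
#' @slot nBscans integer, number of B-scans in the raster.
#' @slot widthMm numeric, physical scan width (mm).
#' @slot pixelDxUm numeric, transverse pixel pitch (um).
#' @slot pixelDzUm numeric, axial pixel pitch (um).
#' @slot foveaCol integer, column index of the fovea.
#' @slot foveaBscan integer, B-scan index through the fovea.
#' @slot ilmZ numeric(nCols), ILM depth (pixels, may be fractional).
#' @slot rpeZ numeric(nCols), inner RPE boundary depth (pixels).
#' @slot rpeBandPx integer, thickness of the depolarizing RPE band (pixels).
#' @slot melanin numeric(nCols), mixture depolarization parameter in [0,1].
#' @slot lipofuscin numeric(nCols), relative SW fluorophore density in [0,1].
#' @slot macularPigment numeric(nCols), SW attenuation factor in [0,1].
#' @slot ezHalfwidthUm numeric, intact-EZ half width each side of the fovea.
#' @slot eye character, "OD" or "OS".
#' @export
setClass("RetinalPhantom",
  representation(
    nCols = "integer", nRows = "integer", nBscans = "integer",
    widthMm = "numeric", pixelDxUm = "numeric", pixelDzUm = "numeric",
    foveaCol = "integer", foveaBscan = "integer",
    ilmZ = "numeric", rpeZ = "numeric", rpeBandPx = "integer",
    melanin = "numeric", lipofuscin = "numeric", macularPigment = "numeric",
    ezHalfwidthUm = "numeric", eye = "character"))

setValidity("RetinalPhantom", function(object) {
  n <- object@nCols
  for (nm in c("ilmZ", "rpeZ", "melanin", "lipofuscin", "macularPigment"))
    if (length(slot(object, nm)) != n)
      return(sprintf("slot '%s' must have length nCols = %d", nm, n))
  for (nm in c("melanin", "lipofuscin", "macularPigment")) {
    v <- slot(object, nm)
    if (any(v < 0 | v > 1))
      return(sprintf("slot '%s' must lie in [0, 1]", nm))
  }
  if (any(object@ilmZ >= object@rpeZ))
    return("ilmZ must be strictly above (smaller than) rpeZ at every column")
  if (any(object@rpeZ + object@rpeBandPx - 1 > object@nRows))
    return("RPE band extends below the last depth row")
  if (any(object@ilmZ < 1))
    return("ilmZ must be >= 1")
  if (abs(object@pixelDxUm * n - object@widthMm * 1000) >
      0.01 * object@widthMm * 1000)
    return("pixelDxUm * nCols must match widthMm within 1%")
  if (!object@eye %in% c("OD", "OS"))
    return("eye must be 'OD' or 'OS'")
  if (object@foveaCol < 1L || object@foveaCol > n)
    return("foveaCol out of range")
  TRUE
})

#' Jones-matrix OCT volume
#'
#' Depth-resolved 2x2 complex Jones matrices for a raster of B-scans.  The
#' matrices are stored vectorised in column-stacking order
#' (J11, J21, J12, J22) as a complex array of dimension
#' `(nRows, nCols, 4, nBscans)`.
#'
#' @slot jones complex array `(z, x, 4, bscan)`.
#' @slot pixelDxUm,pixelDzUm numeric pixel pitches (um).
#' @slot widthMm numeric scan width (mm).
#' @slot eye character, "OD" or "OS".
#' @slot foveaCol integer, fovea column (NA if unknown).
#' @slot foveaBscan integer, fovea B-scan index (NA if unknown).
#' @export
setClass("JonesVolume",
  representation(
    jones = "array", pixelDxUm = "numeric", pixelDzUm = "numeric",
    widthMm = "numeric", eye = "character",
    foveaCol = "integer", foveaBscan = "integer"))

setValidity("JonesVolume", function(object) {
  d <- dim(object@jones)
  if (length(d) != 4L || d[3] != 4L)
    return("jones must be a complex array of dim (z, x, 4, bscan)")
  if (!is.complex(object@jones))
    return("jones must be complex")
  if (anyNA(object@jones))
    return("jones must be finite")
  if (!object@eye %in% c("OD", "OS"))
    return("eye must be 'OD' or 'OS'")
  TRUE
})

#' Local coherency matrix
#'
#' Second-moment matrix `C = <vec(J) vec(J)^H>` of the vectorised Jones
#' matrix (column-stacking order J11, J21, J12, J22) over a local ensemble
#' of pixels.  Hermitian positive-semidefinite; its eigenvalue spectrum
#' quantifies depolarization.
#'
#' @slot C complex 4x4 Hermitian PSD matrix.
#' @slot nSamples integer, number of pixels averaged.
#' @export
setClass("CoherencyMatrix",
  representation(C = "matrix", nSamples = "integer"),
  prototype(C = diag(4) / 4 + 0i, nSamples = 1L))

# internal constructor: the slot name C would partially match the Class
# argument of new(), so slots are filled by assignment
.newCoherency <- function(C, nSamples) {
  obj <- new("CoherencyMatrix")
  obj@C <- C
  obj@nSamples <- as.integer(nSamples)
  validObject(obj)
  obj
}

setValidity("CoherencyMatrix", function(object) {
  C <- object@C
  if (!all(dim(C) == c(4L, 4L)))
    return("C must be 4x4")
  if (max(Mod(C - Conj(t(C)))) > 1e-10 * max(1, max(Mod(C))))
    return("C must be Hermitian to 1e-10")
  lam <- eigen(0.5 * (C + Conj(t(C))), symmetric = TRUE,
               only.values = TRUE)$values
  if (min(lam) < -1e-10 * max(1, max(abs(lam))))
    return("C must be positive-semidefinite")
  if (object@nSamples < 1L)
    return("nSamples must be >= 1")
  TRUE
})

#' Per-pixel polarimetric entropy of one B-scan
#'
#' Entropy values in [0, 1] (base-4 logarithm of the 4-dimensional coherency
#' eigenvalue spectrum); pixels whose corrected coherency has zero trace are
#' `NA`.
#'
#' @slot values numeric matrix (z, x); entries in [0, 1] or NA.
#' @slot kernelZ,kernelX integer kernel dimensions used.
#' @export
setClass("EntropyMap",
  representation(values = "matrix", kernelZ = "integer", kernelX = "integer"))

setValidity("EntropyMap", function(object) {
  v <- object@values
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    return("entropy values must lie in [0, 1]")
  if (object@kernelZ < 1L || object@kernelX < 1L)
    return("kernel dimensions must be positive")
  TRUE
})

#' Segmentation trace of a retinal boundary
#'
#' Per-column depth coordinate of a segmented boundary (RPE or ILM) on one
#' B-scan, defined on a contiguous column interval.  Depths may be
#' fractional.
#'
#' @slot cols integer vector of column indices (1-based, contiguous).
#' @slot z numeric vector of depth coordinates (pixels).
#' @slot boundary character, one of "RPE", "ILM", "EZ".
#' @slot source character, "manual" or "synthetic-truth".
#' @export
setClass("SegTrace",
  representation(cols = "integer", z = "numeric", boundary = "character",
                 source = "character"))

setValidity("SegTrace", function(object) {
  if (length(object@cols) != length(object@z))
    return("cols and z must have equal length")
  if (length(object@cols) &&
      !all(diff(object@cols) == 1L))
    return("cols must be contiguous")
  if (any(object@z < 0))
    return("z must be nonnegative")
  if (!object@boundary %in% c("RPE", "ILM", "EZ"))
    return("boundary must be RPE, ILM or EZ")
  TRUE
})

#' Construct a SegTrace
#'
#' @param cols integer column indices (contiguous).
#' @param z depth coordinates in pixels (may be fractional).
#' @param boundary "RPE", "ILM" or "EZ".
#' @param source "manual" or "synthetic-truth".
#' @return A [SegTrace-class] object.
#' @export
SegTrace <- function(cols, z, boundary = "RPE", source = "manual") {
  new("SegTrace", cols = as.integer(cols), z = as.numeric(z),
      boundary = boundary, source = source)
}

#' Sectioned line profile
#'
#' Mean values (entropy or AF intensity) of a line profile binned into
#' contiguous 0.25-mm sections relative to the fovea.  After orientation
#' (see [orientProfile]) the temporal side always carries negative bin
#' centers.
#'
#' @slot binCenterMm numeric, signed bin centers in mm (0 = foveal section).
#' @slot meanValue numeric, per-bin unweighted mean.
#' @slot nPixels integer, number of columns contributing to each bin.
#' @slot binWidthMm numeric(1), section width (0.25 mm by default).
#' @slot eye character, "OD" or "OS".
#' @slot oriented logical(1), whether temporal-negative orientation has been
#'   applied.
#' @export
setClass("SectionProfile",
  representation(binCenterMm = "numeric", meanValue = "numeric",
                 nPixels = "integer", binWidthMm = "numeric",
                 eye = "character", oriented = "logical"))

setValidity("SectionProfile", function(object) {
  n <- length(object@binCenterMm)
  if (length(object@meanValue) != n || length(object@nPixels) != n)
    return("binCenterMm, meanValue and nPixels must have equal length")
  if (n > 1L) {
    d <- diff(sort(object@binCenterMm))
    if (any(abs(d - object@binWidthMm) > 1e-9))
      return("bins must be contiguous with spacing binWidthMm")
  }
  if (!object@eye %in% c("OD", "OS"))
    return("eye must be 'OD' or 'OS'")
  TRUE
})

#' Sectioned autofluorescence profile
#'
#' A [SectionProfile-class] carrying AF intensity for one modality, with a
#' flag recording per-eye min-max normalization.
#'
#' @slot modality character, "SW" or "NIR".
#' @slot normalized logical(1).
#' @export
setClass("AFProfile", contains = "SectionProfile",
  representation(modality = "character", normalized = "logical"))

setValidity("AFProfile", function(object) {
  if (!object@modality %in% c("SW", "NIR"))
    return("modality must be 'SW' or 'NIR'")
  if (object@normalized) {
    v <- object@meanValue
    if (abs(min(v) - 0) > 1e-9 || abs(max(v) - 1) > 1e-9)
      return("normalized profile must have min 0 and max 1")
  }
  TRUE
})

#' 2-D affine transform
#'
#' Maps points as `A %*% p + b` where `p = c(x, y)`.
#'
#' @slot A numeric 2x2 linear part (must be nonsingular).
#' @slot b numeric length-2 offset.
#' @slot rmsResidual numeric(1), RMS landmark fit residual in pixels.
#' @export
setClass("AffineTransform2D",
  representation(A = "matrix", b = "numeric", rmsResidual = "numeric"),
  prototype(A = diag(2), b = c(0, 0), rmsResidual = 0))

setValidity("AffineTransform2D", function(object) {
  if (!all(dim(object@A) == c(2L, 2L)))
    return("A must be 2x2")
  if (abs(det(object@A)) < 1e-12)
    return("A must be nonsingular")
  if (length(object@b) != 2L)
    return("b must have length 2")
  if (object@rmsResidual < 0)
    return("rmsResidual must be >= 0")
  TRUE
})

#' Construct an AffineTransform2D
#'
#' @param A 2x2 linear part.
#' @param b length-2 offset.
#' @param rmsResidual landmark fit residual (pixels).
#' @return An [AffineTransform2D-class] object.
#' @examples
#' identityTransform <- AffineTransform2D()
#' @export
AffineTransform2D <- function(A = diag(2), b = c(0, 0), rmsResidual = 0) {
  new("AffineTransform2D", A = A, b = as.numeric(b),
      rmsResidual = as.numeric(rmsResidual))
}

#' Simulated autofluorescence scene
#'
#' A grayscale AF image together with the true affine transform that maps
#' OCT en-face coordinates `(x = column, y = B-scan)` to AF pixel
#' coordinates, and matched landmark pairs.
#'
#' @slot image numeric matrix (rows = y, cols = x), nonnegative.
#' @slot modality character, "SW" or "NIR".
#' @slot trueTransform [AffineTransform2D-class] en-face -> AF.
#' @slot landmarks data.frame with columns `x_enface, y_enface, x_af, y_af`.
#' @export
setClass("AFScene",
  representation(image = "matrix", modality = "character",
                 trueTransform = "AffineTransform2D",
                 landmarks = "data.frame"))

setValidity("AFScene", function(object) {
  if (any(object@image < 0))
    return("image must be nonnegative")
  if (!object@modality %in% c("SW", "NIR"))
    return("modality must be 'SW' or 'NIR'")
  need <- c("x_enface", "y_enface", "x_af", "y_af")
  if (!all(need %in% names(object@landmarks)))
    return("landmarks must have columns x_enface, y_enface, x_af, y_af")
  if (nrow(object@landmarks) < 4L)
    return("at least 4 landmark pairs are required")
  TRUE
})
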