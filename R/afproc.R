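#' @include AllGenerics.R
NULL

#' Apply an affine transform to points
#'
#' @param transform an [AffineTransform2D-class].
#' @param points numeric N x 2 matrix (columns x, y) or length-2 vector.
#' @return Transformed N x 2 matrix.
#' @export
applyTransform <- function(transform, points) {
  stopifnot(is(transform, "AffineTransform2D"))
  p <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  t(transform@A %*% t(p) + transform@b)
}

#' Fit an affine transform to landmark pairs
#'
#' Least-squares affine registration from matched characteristic points
#' (e.g. vessel bifurcations): finds `A`, `b` minimising
#' `sum || A src_i + b - dst_i ||^2`.  Requires at least 3 non-collinear
#' pairs; the RMS residual is reported on the fitted transform.
#'
#' @param src,dst numeric N x 2 matrices of matched points (columns x, y),
#'   or data.frames with two columns.
#' @return An [AffineTransform2D-class].
#' @examples
#' src <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1))
#' fitLandmarkTransform(src, src + 5)   # pure translation
#' @export
fitLandmarkTransform <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) != nrow(dst) || ncol(src) != 2L || ncol(dst) != 2L)
    stop("src and dst must be matched N x 2 matrices")
  if (nrow(src) < 3L)
    stop("at least 3 landmark pairs are required")
  X <- cbind(src, 1)
  if (qr(X)$rank < 3L)
    stop("landmarks are collinear; affine fit is degenerate")
  coef <- qr.solve(X, dst)           # 3 x 2: rows (a_x, a_y, b)
  A <- t(coef[1:2, , drop = FALSE])  # 2 x 2
  b <- as.numeric(coef[3, ])
  fit <- X %*% coef
  rms <- sqrt(mean(rowSums((fit - dst)^2)))
  AffineTransform2D(A = A, b = b, rmsResidual = rms)
}

# bilinear sample of image (rows = y, cols = x) at continuous (x, y);
# out-of-bounds -> 0
.bilinear <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  val <- function(xi, yi) {
    ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
    v <- numeric(length(xi))
    v[ok] <- image[cbind(yi[ok], xi[ok])]
    v
  }
  val(x0, y0) * (1 - fx) * (1 - fy) +
    val(x0 + 1, y0) * fx * (1 - fy) +
    val(x0, y0 + 1) * (1 - fx) * fy +
    val(x0 + 1, y0 + 1) * fx * fy
}

#' Warp an image through an affine transform
#'
#' Inverse-mapped resampling: output pixel `(x, y)` takes the bilinearly
#' interpolated value of the input image at `transform(x, y)`.  Sampling
#' positions outside the input map to 0.  Warping an AF image with the
#' en-face-to-AF transform therefore resamples it onto the OCT en-face
#' grid.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param transform an [AffineTransform2D-class] mapping output coordinates
#'   to input coordinates.
#' @param outShape integer c(rows, cols) of the output.
#' @return Numeric matrix of dimension `outShape`.
#' @export
warpImage <- function(image, transform, outShape) {
  stopifnot(is(transform, "AffineTransform2D"), length(outShape) == 2L)
  nrOut <- outShape[1]; ncOut <- outShape[2]
  x <- rep(seq_len(ncOut), each = nrOut)
  y <- rep(seq_len(nrOut), times = ncOut)
  p <- applyTransform(transform, cbind(x, y))
  matrix(.bilinear(image, p[, 1], p[, 2]), nrOut, ncOut)
}

#' AF intensity profile along the RPE-corresponding line
#'
#' Samples a registered AF image (already resampled onto the OCT en-face
#' grid) along the horizontal line corresponding to the B-scan through the
#' fovea, then bins the per-column intensities into 0.25-mm sections
#' exactly as the entropy profile ([binSections]).  A single row is
#' sampled, with no vertical averaging.
#'
#' @param image registered AF image in the en-face frame (rows = B-scan,
#'   cols = A-scan).
#' @param row line to sample (the foveal B-scan row).
#' @param foveaCol fovea column index.
#' @param pixelDxUm transverse pitch (um).
#' @param modality "SW" or "NIR".
#' @param eye "OD" or "OS".
#' @param binWidthMm section width (default 0.25 mm).
#' @return An unoriented, unnormalized [AFProfile-class].
#' @export
afLineProfile <- function(image, row, foveaCol, pixelDxUm,
                          modality = c("NIR", "SW"), eye = "OD",
                          binWidthMm = 0.25) {
  modality <- match.arg(modality)
  if (row < 1L || row > nrow(image))
    stop("row outside the registered image")
  sp <- binSections(image[row, ], foveaCol, pixelDxUm,
                    binWidthMm = binWidthMm, eye = eye)
  new("AFProfile", binCenterMm = sp@binCenterMm, meanValue = sp@meanValue,
      nPixels = sp@nPixels, binWidthMm = sp@binWidthMm, eye = sp@eye,
      oriented = FALSE, modality = modality, normalized = FALSE)
}

#' Per-eye min-max normalization of an AF profile
#'
#' Simplified internal AF reference: within each eye the maximum section
#' intensity is mapped to 1 and the minimum to 0,
#' `(v - min) / (max - min)`, making AF intensities comparable across
#' participants.  Invariant under positive affine rescaling of the inputs
#' and idempotent.
#'
#' @param profile an [AFProfile-class] with at least 2 sections and
#'   `max > min`.
#' @return The normalized profile.
#' @export
minmaxNormalize <- function(profile) {
  stopifnot(is(profile, "AFProfile"))
  v <- profile@meanValue
  if (length(v) < 2L)
    stop("profile must have at least 2 sections")
  rng <- range(v, na.rm = TRUE)
  if (rng[2] <= rng[1])
    stop("degenerate profile: max equals min")
  out <- profile
  out@meanValue <- (v - rng[1]) / (rng[2] - rng[1])
  out@normalized <- TRUE
  out
}
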