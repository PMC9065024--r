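#' @include AllGenerics.R
NULL

#' Vectorise a 2x2 Jones matrix
#'
#' Column-stacking order: `c(J[1,1], J[2,1], J[1,2], J[2,2])`.  The entropy
#' is invariant to the vectorisation convention, but coherency round-trips
#' require one fixed order, which is this one throughout the package.
#'
#' @param J a 2x2 complex matrix.
#' @return A complex 4-vector.
#' @export
vecJones <- function(J) {
  stopifnot(all(dim(J) == c(2L, 2L)))
  as.complex(as.vector(J))
}

#' Coherency matrix of a pixel ensemble
#'
#' Averages the outer products `vec(J) vec(J)^H` over a window of Jones
#' matrices: `C = (1/N) sum_i t_i t_i^H`.  The result is Hermitian
#' positive-semidefinite by construction.
#'
#' @param window a list of 2x2 complex matrices, a complex array of dim
#'   `(2, 2, N)`, or a 4 x N matrix of already-vectorised Jones matrices.
#' @return A [CoherencyMatrix-class].
#' @examples
#' J <- matrix(c(1, 0, 0, 1i), 2)
#' coherencyMatrix(list(J))        # rank-1
#' @export
coherencyMatrix <- function(window) {
  if (is.list(window)) {
    if (length(window) == 0L) stop("empty window")
    T <- vapply(window, vecJones, complex(4))
  } else if (is.array(window) && length(dim(window)) == 3L) {
    if (dim(window)[3] == 0L) stop("empty window")
    T <- apply(window, 3, as.vector)
  } else if (is.matrix(window) && nrow(window) == 4L) {
    if (ncol(window) == 0L) stop("empty window")
    T <- window
  } else {
    stop("window must be a list/array of 2x2 matrices or a 4 x N matrix")
  }
  T <- matrix(as.complex(T), nrow = 4)
  if (anyNA(T) || any(!is.finite(Mod(T))))
    stop("window contains non-finite Jones matrices")
  C <- (T %*% Conj(t(T))) / ncol(T)
  C <- 0.5 * (C + Conj(t(C)))
  .newCoherency(C, ncol(T))
}

#' Polarimetric entropy of a coherency matrix
#'
#' Eigenvalues of the 4x4 coherency matrix are clipped at zero and
#' trace-normalised to probabilities `p_i`; the entropy is
#' `E = -sum p_i log4(p_i)` with `0 log 0 = 0`.  The base-4 logarithm
#' normalises the range to [0, 1]: 0 for a rank-one (fully polarized)
#' ensemble, 1 for the maximally mixed coherency `I/4` (completely random
#' polarization).  A matrix with zero trace (no signal) yields `NA`, the
#' invalid-pixel marker, rather than an error.
#'
#' @param C a [CoherencyMatrix-class] or a 4x4 complex Hermitian matrix.
#' @return Entropy in [0, 1], or `NA` for zero trace.
#' @examples
#' entropyFromCoherency(diag(4) / 4)  # 1
#' @export
entropyFromCoherency <- function(C) {
  M <- if (is(C, "CoherencyMatrix")) C@C else C
  stopifnot(all(dim(M) == c(4L, 4L)))
  M <- 0.5 * (M + Conj(t(M)))
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  s <- sum(lam)
  if (s <= 0 || !is.finite(s)) return(NA_real_)
  p <- lam / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(4)
}

#' Additive-noise bias correction of a coherency matrix
#'
#' Additive circular complex noise of power `sigma2` per Jones element
#' contributes `sigma2 * I` to the expected coherency; subtracting it
#' removes the upward entropy bias on strongly polarized pixels.  Negative
#' eigenvalues arising from the subtraction are clipped to zero (minimal
#' perturbation restoring positive-semidefiniteness); trace
#' re-normalisation is deferred to the entropy computation.
#'
#' @param C a [CoherencyMatrix-class].
#' @param sigma2 noise power per element (>= 0).
#' @return A corrected [CoherencyMatrix-class].
#' @export
noiseBiasCorrect <- function(C, sigma2) {
  stopifnot(is(C, "CoherencyMatrix"))
  if (length(sigma2) != 1L || is.na(sigma2) || sigma2 < 0)
    stop("sigma2 must be a single nonnegative value")
  if (sigma2 == 0) return(C)
  M <- C@C - diag(sigma2, 4)
  e <- eigen(0.5 * (M + Conj(t(M))), symmetric = TRUE)
  lam <- pmax(e$values, 0)
  M2 <- e$vectors %*% diag(lam) %*% Conj(t(e$vectors))
  .newCoherency(0.5 * (M2 + Conj(t(M2))), C@nSamples)
}

#' Estimate additive-noise power from a signal-free region
#'
#' Averages `|element|^2` over the four Jones elements of a user-designated
#' signal-free region (typically rows above the ILM, where only sensor
#' noise is present).  The result is the per-element noise power `sigma2`
#' consumed by [noiseBiasCorrect] and [entropyMap].
#'
#' @param volume a [JonesVolume-class].
#' @param bscanIndex B-scan to use.
#' @param rows depth rows of the signal-free region.
#' @return Estimated noise power per element.
#' @export
estimateNoiseSigma2 <- function(volume, bscanIndex = 1L, rows) {
  stopifnot(is(volume, "JonesVolume"))
  d <- dim(volume@jones)
  if (bscanIndex < 1L || bscanIndex > d[4]) stop("bscanIndex out of range")
  if (any(rows < 1L | rows > d[1])) stop("rows out of range")
  mean(Mod(volume@jones[rows, , , bscanIndex])^2)
}

#' Per-pixel polarimetric entropy map of one B-scan
#'
#' Computes the entropy at every pixel from the coherency matrix averaged
#' over a kernel centred on the pixel (default 5 x 11, depth x transverse).
#' Kernels are truncated at the image borders: the mean runs over the
#' available pixels only, with no padding (padding would fabricate
#' polarization states).  With `correctNoise = TRUE`, `sigma2 * I` is
#' subtracted from every local coherency before eigen-decomposition;
#' `sigma2` may be given directly or estimated from signal-free rows via
#' `noiseRows`.
#'
#' @param volume a [JonesVolume-class].
#' @param bscanIndex B-scan to process.
#' @param kernelZ,kernelX odd kernel dimensions (defaults 5 and 11).
#' @param correctNoise subtract the additive-noise term (default `FALSE`).
#' @param sigma2 noise power per element; required if `correctNoise` and
#'   `noiseRows` is missing.
#' @param noiseRows rows of a signal-free region used to estimate `sigma2`.
#' @return An [EntropyMap-class].
#' @examples
#' ph <- makePhantom(nCols = 64, nRows = 120, nBscans = 1)
#' vol <- renderJonesVolume(ph, NoiseSpec(snrDb = Inf), bscans = 1L)
#' em <- entropyMap(vol, 1L)
#' @export
entropyMap <- function(volume, bscanIndex = 1L, kernelZ = 5L, kernelX = 11L,
                       correctNoise = FALSE, sigma2 = NULL,
                       noiseRows = NULL) {
  stopifnot(is(volume, "JonesVolume"))
  d <- dim(volume@jones)
  if (bscanIndex < 1L || bscanIndex > d[4]) stop("bscanIndex out of range")
  if (kernelZ < 1L || kernelX < 1L || kernelZ %% 2L != 1L ||
      kernelX %% 2L != 1L)
    stop("kernel dimensions must be odd and positive")
  if (kernelZ > d[1] || kernelX > d[2])
    stop("kernel larger than the image")
  s2 <- 0
  if (correctNoise) {
    s2 <- if (!is.null(sigma2)) sigma2
          else if (!is.null(noiseRows))
            estimateNoiseSigma2(volume, bscanIndex, noiseRows)
          else stop("correctNoise needs sigma2 or noiseRows")
    if (s2 < 0) stop("sigma2 must be >= 0")
  }
  T <- volume@jones[, , , bscanIndex, drop = FALSE]
  vals <- cpp_entropy_map(as.complex(T), d[1], d[2],
                          as.integer(kernelZ), as.integer(kernelX),
                          as.numeric(s2))
  vals[vals < 0 & vals > -1e-12] <- 0
  vals[vals > 1 & vals < 1 + 1e-12] <- 1
  new("EntropyMap", values = vals, kernelZ = as.integer(kernelZ),
      kernelX = as.integer(kernelX))
}

#' OCT intensity image of one B-scan
#'
#' Per-pixel intensity is the sum of squared moduli of the four Jones
#' elements.
#'
#' @param volume a [JonesVolume-class].
#' @param bscanIndex B-scan to extract.
#' @return A nonnegative numeric matrix (z, x).
#' @export
intensityBScan <- function(volume, bscanIndex = 1L) {
  stopifnot(is(volume, "JonesVolume"))
  d <- dim(volume@jones)
  if (bscanIndex < 1L || bscanIndex > d[4]) stop("bscanIndex out of range")
  M <- Mod(volume@jones[, , , bscanIndex, drop = FALSE])^2
  dim(M) <- d[1:3]
  apply(M, c(1, 2), sum)
}

#' En-face maximum intensity projection
#'
#' Projects the raster-scanned volume to a 2-D en-face image by taking,
#' for each (B-scan, column) position, the maximum of the OCT intensity
#' over depth.
#'
#' @param volume a [JonesVolume-class].
#' @return A numeric matrix (bscan, x).
#' @export
enFaceMIP <- function(volume) {
  stopifnot(is(volume, "JonesVolume"))
  d <- dim(volume@jones)
  out <- matrix(0, d[4], d[2])
  for (b in seq_len(d[4])) {
    I <- intensityBScan(volume, b)
    out[b, ] <- apply(I, 2, max)
  }
  out
}
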