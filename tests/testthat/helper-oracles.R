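# Independent oracles and small fixture builders used across the suite.

# random 4x4 Hermitian PSD matrix (complex Wishart-like)
randomPSD <- function(k = 6) {
  A <- matrix(complex(real = rnorm(4 * k), imaginary = rnorm(4 * k)), 4, k)
  C <- (A %*% Conj(t(A))) / k
  0.5 * (C + Conj(t(C)))
}

# independent entropy evaluation: eigenvalues by SVD (Hermitian PSD =>
# singular values are the eigenvalues), then the base-4 formula directly
svdEntropy <- function(C) {
  lam <- svd(C)$d
  lam <- pmax(lam, 0)
  s <- sum(lam)
  if (s <= 0) return(NA_real_)
  p <- lam / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(4)
}

# brute-force two-sided exact Mann-Whitney p-value by enumerating every
# assignment of the pooled ranks to group a
bruteRankSumP <- function(a, b) {
  na <- length(a); n <- na + length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- combn(n, na)
  u <- apply(combos, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  lower <- mean(u <= uObs)
  upper <- mean(u >= uObs)
  min(1, 2 * min(lower, upper))
}

# brute-force exact two-sided permutation p for Spearman rho (small n)
bruteSpearmanP <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  P <- perms(ry)
  stat <- apply(P, 1, function(p) abs(cor(rx, p)))
  mean(stat >= obs - 1e-12)
}

# a compact phantom that renders quickly
smallPhantom <- function(nCols = 128L, nRows = 140L, ...) {
  makePhantom(nCols = nCols, nRows = nRows, nBscans = 1L, ...)
}

# wrap a complex (z, x, 4, b) array as a JonesVolume
makeVolume <- function(arr, dxUm = 5.86, dzUm = 4.2, eye = "OD",
                       foveaCol = dim(arr)[2] %/% 2L) {
  new("JonesVolume", jones = arr, pixelDxUm = dxUm, pixelDzUm = dzUm,
      widthMm = dim(arr)[2] * dxUm / 1000, eye = eye,
      foveaCol = as.integer(foveaCol), foveaBscan = 1L)
}

# constant-profile builder
flatProfile <- function(values, centers = (seq_along(values) -
                          (length(values) + 1) / 2) * 0.25,
                        eye = "OD", oriented = TRUE) {
  new("SectionProfile", binCenterMm = centers, meanValue = values,
      nPixels = rep(42L, length(values)), binWidthMm = 0.25, eye = eye,
      oriented = oriented)
}

afProfileFrom <- function(values, centers = (seq_along(values) -
                            (length(values) + 1) / 2) * 0.25,
                          modality = "NIR", eye = "OD", oriented = TRUE) {
  new("AFProfile", binCenterMm = centers, meanValue = values,
      nPixels = rep(42L, length(values)), binWidthMm = 0.25, eye = eye,
      oriented = oriented, modality = modality, normalized = FALSE)
}
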