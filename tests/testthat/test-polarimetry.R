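test_that("coherency construction averages outer products", {
  J <- matrix(c(1, 0, 0, 1i), 2)
  C1 <- coherencyMatrix(list(J))
  expect_equal(C1@nSamples, 1L)
  lam <- eigen(C1@C, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(lam[1], 2, tolerance = 1e-12)       # trace = |J|_F^2
  expect_lt(max(abs(lam[2:4])), 1e-12)             # rank 1

  C2 <- coherencyMatrix(list(J, J))                # duplicate = same mean
  expect_equal(C2@C, C1@C, tolerance = 1e-14)

  # two orthonormal target vectors, equal weight -> eigenvalues .5/.5/0/0
  T <- cbind(c(1, 0, 0, 0), c(0, 1, 0, 0)) + 0i
  C3 <- coherencyMatrix(T)
  lam3 <- eigen(C3@C, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(lam3, c(0.5, 0.5, 0, 0), tolerance = 1e-12)

  expect_error(coherencyMatrix(list()), "empty")
})

test_that("entropy of a coherency matrix spans [0, 1] with analytic
           anchor points", {
  t0 <- c(1, 2i, -1, 0.5) / sqrt(6.25)
  expect_equal(entropyFromCoherency(t0 %*% Conj(t(t0))), 0)
  expect_equal(entropyFromCoherency(diag(4) / 4 + 0i), 1)
  expect_equal(entropyFromCoherency(diag(c(0.625, 0.125, 0.125, 0.125))),
               closedFormEntropy(0.5), tolerance = 1e-12)
  expect_true(is.na(entropyFromCoherency(matrix(0i, 4, 4))))
})

test_that("entropy agrees with an independent spectral evaluation on
           random PSD matrices", {
  set.seed(101)
  Cs <- replicate(200, randomPSD(), simplify = FALSE)
  for (C in Cs) {
    expect_lt(abs(entropyFromCoherency(C) - svdEntropy(C)), 1e-10)
    e <- entropyFromCoherency(C)
    expect_gte(e, 0); expect_lte(e, 1)
  }
  # the batch (compiled) path agrees with the R path
  cube <- array(0i, c(4, 4, length(Cs)))
  for (i in seq_along(Cs)) cube[, , i] <- Cs[[i]]
  batch <- rpeEntropy:::cpp_entropy_batch(cube)
  rpath <- vapply(Cs, entropyFromCoherency, numeric(1))
  expect_lt(max(abs(batch - rpath)), 1e-10)
})

test_that("noise-bias correction removes an exactly known additive term
           and reduces bias on simulated noisy kernels", {
  t0 <- c(0.5, 0.5, 0.5i, -0.5)
  C <- coherencyMatrix(matrix(t0, 4))
  expect_identical(noiseBiasCorrect(C, 0), C)

  noisy <- .5 * (C@C + Conj(t(C@C))) + diag(0.03, 4)
  Cn <- rpeEntropy:::.newCoherency(noisy, 1L)
  expect_equal(entropyFromCoherency(noiseBiasCorrect(Cn, 0.03)), 0,
               tolerance = 1e-9)
  expect_error(noiseBiasCorrect(C, -1), "nonnegative")

  # Monte-Carlo: pure-polarization kernels at 20 dB SNR
  set.seed(7)
  sigma2 <- 10^(-20 / 10) / 4
  biasU <- biasC <- numeric(100)
  for (k in 1:100) {
    amp <- complex(real = rnorm(55, sd = sqrt(0.5)),
                   imaginary = rnorm(55, sd = sqrt(0.5)))
    T <- outer(c(1, 0, 0, 0) + 0i, amp) +
      matrix(complex(real = rnorm(220, sd = sqrt(sigma2 / 2)),
                     imaginary = rnorm(220, sd = sqrt(sigma2 / 2))), 4)
    Ck <- coherencyMatrix(T)
    biasU[k] <- entropyFromCoherency(Ck)
    biasC[k] <- entropyFromCoherency(noiseBiasCorrect(Ck, sigma2))
  }
  expect_lte(mean(biasC), mean(biasU))
})

test_that("entropy maps are zero for uniform polarization and for 1x1
           kernels, and validate their kernel arguments", {
  arr <- array(0i, c(20, 30, 4, 1))
  for (k in 1:4) arr[, , k, 1] <- c(1, 0, 1i, 0)[k]
  vol <- makeVolume(arr)
  em <- entropyMap(vol, 1L, 5L, 11L)
  expect_lt(max(entropyValues(em)), 1e-9)

  # per-pixel (1x1) coherency is rank one whatever the content
  set.seed(3)
  arr2 <- array(complex(real = rnorm(20 * 30 * 4),
                        imaginary = rnorm(20 * 30 * 4)), c(20, 30, 4, 1))
  em2 <- entropyMap(makeVolume(arr2), 1L, 1L, 1L)
  expect_lt(max(entropyValues(em2)), 1e-9)

  expect_error(entropyMap(vol, 1L, 4L, 11L), "odd")
  expect_error(entropyMap(vol, 1L, 5L, 31L), "larger")
  expect_error(entropyMap(vol, 2L), "out of range")
})

test_that("entropy map equals the per-window R computation including
           truncated borders", {
  set.seed(9)
  nz <- 14L; nx <- 17L
  arr <- array(complex(real = rnorm(nz * nx * 4),
                       imaginary = rnorm(nz * nx * 4)), c(nz, nx, 4, 1))
  vol <- makeVolume(arr)
  s2 <- 0.01
  em <- entropyMap(vol, 1L, 3L, 5L, correctNoise = TRUE, sigma2 = s2)
  v <- entropyValues(em)
  for (i in c(1L, 2L, 7L, nz)) {
    for (j in c(1L, 3L, 9L, nx)) {
      rows <- max(1, i - 1):min(nz, i + 1)
      cols <- max(1, j - 2):min(nx, j + 2)
      T <- matrix(0i, 4, 0)
      for (cc in cols) T <- cbind(T, t(arr[rows, cc, , 1]))
      ref <- entropyFromCoherency(noiseBiasCorrect(coherencyMatrix(T), s2))
      expect_equal(v[i, j], ref, tolerance = 1e-10)
    }
  }
})

test_that("entropy is invariant under unitary transformation of the
           Jones matrices", {
  set.seed(21)
  nz <- 12L; nx <- 15L
  arr <- array(complex(real = rnorm(nz * nx * 4),
                       imaginary = rnorm(nz * nx * 4)), c(nz, nx, 4, 1))
  # random unitaries U, V; J -> U J V acts on vec(J) as (t(V) %x% U)
  qrU <- qr(matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2))
  U <- qr.Q(qrU)
  qrV <- qr(matrix(complex(real = rnorm(4), imaginary = rnorm(4)), 2))
  V <- qr.Q(qrV)
  K <- t(V) %x% U
  arr2 <- array(0i, dim(arr))
  for (i in seq_len(nz)) for (j in seq_len(nx))
    arr2[i, j, , 1] <- K %*% arr[i, j, , 1]
  e1 <- entropyValues(entropyMap(makeVolume(arr), 1L, 3L, 5L))
  e2 <- entropyValues(entropyMap(makeVolume(arr2), 1L, 3L, 5L))
  expect_lt(max(abs(e1 - e2)), 1e-10)
})

test_that("estimated band entropy increases with the mixture parameter",
{
  est <- vapply(c(0.2, 0.5, 0.8), function(m) {
    ph <- smallPhantom(nCols = 256L, melaninPreset = "flat",
                       melaninFlat = m)
    vol <- renderJonesVolume(ph, NoiseSpec(seed = 31), bscans = 1L)
    em <- entropyMap(vol, 1L, correctNoise = TRUE, noiseRows = 1:11)
    v <- entropyValues(em)
    rpe0 <- round(ph@rpeZ)
    mean(vapply(seq_len(256L), function(c)
      mean(v[(rpe0[c] + 2):(rpe0[c] + 5), c]), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_lt(abs(est[2] - closedFormEntropy(0.5)), 0.05)
})

test_that("intensity and en-face projection follow their definitions", {
  arr <- array(0i, c(3, 4, 4, 2))
  vol <- makeVolume(arr)
  expect_true(all(intensityBScan(vol, 1L) == 0))

  arr[2, 3, , 1] <- c(1, 0, 0, 1)   # identity Jones matrix
  vol <- makeVolume(arr)
  expect_equal(intensityBScan(vol, 1L)[2, 3], 2)

  expect_equal(intensityBScan(makeVolume(arr * 2), 1L)[2, 3], 8)

  # MIP picks the bright voxel regardless of depth
  set.seed(5)
  arr3 <- array(complex(real = rnorm(6 * 5 * 4, sd = 0.01)), c(6, 5, 4, 1))
  depth <- sample(6, 5, replace = TRUE)
  for (j in 1:5) arr3[depth[j], j, 1, 1] <- 10
  mip <- enFaceMIP(makeVolume(arr3))
  I <- intensityBScan(makeVolume(arr3), 1L)
  expect_equal(mip[1, ], apply(I, 2, max))
  expect_true(all(mip[1, ] >= 100))

  # single-depth volume: MIP equals the intensity image
  arr4 <- arr3[1, , , , drop = FALSE]
  dim(arr4) <- c(1, 5, 4, 1)
  expect_equal(enFaceMIP(makeVolume(arr4))[1, ],
               intensityBScan(makeVolume(arr4), 1L)[1, ])
})
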