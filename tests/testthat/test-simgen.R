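test_that("phantom presets satisfy their defining shapes and invariants", {
  ph <- smallPhantom()
  m <- melaninProfile(ph)
  expect_equal(which.max(m), ph@foveaCol)
  d <- abs(seq_along(m) - ph@foveaCol)
  expect_true(all(diff(m[order(d)]) <= 1e-12))  # non-increasing from fovea
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(ph@ilmZ < ph@rpeZ))
  expect_lt(abs(ph@pixelDxUm * ph@nCols - ph@widthMm * 1000),
            0.01 * ph@widthMm * 1000)

  flat <- smallPhantom(melaninPreset = "flat", melaninFlat = 0.3)
  expect_true(all(melaninProfile(flat) == 0.3))

  expect_identical(smallPhantom(), smallPhantom())  # deterministic

  # geometry that cannot fit: retina thicker than the depth range
  expect_error(smallPhantom(nRows = 60L), "geometry")
})

test_that("closed-form mixture entropy matches hand values and is monotone", {
  expect_equal(closedFormEntropy(0), 0)
  expect_equal(closedFormEntropy(1), 1)
  expect_equal(closedFormEntropy(0.5), 0.7743975, tolerance = 1e-6)
  grid <- closedFormEntropy(seq(0, 1, by = 0.05))
  expect_true(all(diff(grid) > 0))
  expect_error(closedFormEntropy(-0.1), "\\[0, 1\\]")
  expect_error(closedFormEntropy(1.1), "\\[0, 1\\]")
})

test_that("degenerate mixture m = 0 without speckle or noise gives a fixed
           target vector across the RPE band", {
  ph <- smallPhantom(melaninPreset = "flat", melaninFlat = 0)
  vol <- renderJonesVolume(ph, NoiseSpec(snrDb = Inf, speckle = FALSE,
                                         seed = 1), bscans = 1L)
  J <- jonesArray(vol)
  rpe0 <- round(ph@rpeZ)
  for (col in c(10L, 64L, 120L)) {
    band <- J[rpe0[col]:(rpe0[col] + ph@rpeBandPx - 1L), col, , 1]
    expect_lt(max(abs(sweep(band, 2, band[1, ], "-"))), 1e-12)
  }
})

# sample coherency of >= 1e4 RPE pixels sharing one target vector: a
# single column observed over many B-scans
bandCoherency <- function(m, seed, nBscans = 1250L) {
  ph <- makePhantom(nCols = 8L, nRows = 120L, nBscans = nBscans,
                    melaninPreset = "flat", melaninFlat = m)
  vol <- renderJonesVolume(ph, NoiseSpec(snrDb = Inf, speckle = FALSE,
                                         seed = seed))
  J <- jonesArray(vol)
  col <- 4L
  rpe0 <- round(ph@rpeZ)[col]
  rows <- rpe0:(rpe0 + ph@rpeBandPx - 1L)
  T <- matrix(0i, 4, 0)
  for (b in seq_len(nBscans))
    T <- cbind(T, t(J[rows, col, , b]))
  stopifnot(ncol(T) >= 1e4)
  (T %*% Conj(t(T))) / ncol(T)
}

test_that("fully depolarized band has isotropic sample coherency", {
  Chat <- bandCoherency(1, seed = 11)
  expect_lte(max(Mod(Chat - diag(4) / 4)), 0.02)
})

test_that("mixture coherency eigenvalues match the closed form across m", {
  for (m in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    C <- bandCoherency(m, seed = round(100 * m))
    lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    lam <- lam / sum(lam)
    expected <- c((1 - m) + m / 4, rep(m / 4, 3))
    expect_lt(max(abs(sort(lam, decreasing = TRUE) -
                      sort(expected, decreasing = TRUE))), 0.02)
  }
})

test_that("volume rendering is bit-identical for a fixed seed", {
  ph <- smallPhantom()
  v1 <- renderJonesVolume(ph, NoiseSpec(seed = 42), bscans = 1L)
  v2 <- renderJonesVolume(ph, NoiseSpec(seed = 42), bscans = 1L)
  expect_identical(jonesArray(v1), jonesArray(v2))
  v3 <- renderJonesVolume(ph, NoiseSpec(seed = 43), bscans = 1L)
  expect_false(identical(jonesArray(v1), jonesArray(v3)))
})

test_that("SW scene with full macular-pigment attenuation is dark at the
           fovea, and a flat-melanin NIR scene is constant", {
  ph <- smallPhantom(macularPigmentPeak = 1)
  sw <- renderAFScene(ph, "SW", noise = NoiseSpec(snrDb = Inf, seed = 2))
  foveaAf <- applyTransform(sw@trueTransform,
                            c(ph@foveaCol, ph@foveaBscan))
  # darkest point of the scene: residual reflects only sub-pixel offset
  # from the exact foveal center (noise is disabled)
  val <- sw@image[round(foveaAf[2]), round(foveaAf[1])]
  expect_lt(val, 0.01)
  expect_gt(max(sw@image), 0.5)   # the ring is bright by contrast

  phFlat <- smallPhantom(melaninPreset = "flat", melaninFlat = 0.4)
  nir <- renderAFScene(phFlat, "NIR", noise = NoiseSpec(snrDb = Inf,
                                                        seed = 2))
  expect_lt(diff(range(nir@image)), 1e-10)
})

test_that("landmarks map exactly under the true transform before jitter", {
  ph <- smallPhantom()
  sc <- renderAFScene(ph, "NIR",
                      misalignment = list(rotationDeg = 3, scale = 1.02,
                                          translatePx = c(5, -8)),
                      noise = NoiseSpec(snrDb = Inf, seed = 3))
  mapped <- applyTransform(sc@trueTransform,
                           as.matrix(sc@landmarks[, c("x_enface",
                                                      "y_enface")]))
  expect_lt(max(abs(mapped -
                    as.matrix(sc@landmarks[, c("x_af", "y_af")]))), 1e-9)
  expect_error(renderAFScene(ph, "NIR", nLandmarks = 3), "landmark")
})

test_that("synthetic cohorts honour the observed clinical ranges and are
           reproducible", {
  cs <- makeCohort(12, seed = 7)
  expect_equal(nrow(cs$cohort), 12L)
  expect_true(all(cs$cohort$ez_width_um >= 650 &
                  cs$cohort$ez_width_um <= 3890))
  expect_true(all(cs$cohort$age >= 24 & cs$cohort$age <= 68))
  expect_true(all(cs$cohort$crt_um >= 182 & cs$cohort$crt_um <= 271))
  validateCohort(cs$cohort)

  cs2 <- makeCohort(12, seed = 7)
  expect_identical(cs$cohort, cs2$cohort)

  one <- makeCohort(1, seed = 3)
  expect_equal(nrow(one$cohort), 1L)
  s <- summarizeCohort(one$cohort)
  expect_equal(s$mean[s$variable == "age"], one$cohort$age)
  expect_true(all(is.na(s$sd)))
})
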