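#' @include AllGenerics.R
NULL

# deterministic unit target vector for column `col` of `nCols`; varies
# smoothly across the scan so that coherency is column-dependent but
# rank-one in the absence of depolarization
.targetVector <- function(col, nCols, phase = 0) {
  a <- pi * col / nCols + phase
  b <- 2 * pi * col / nCols
  t <- rbind(cos(a), sin(a) * exp(1i * b), 0.4 * exp(1i * a),
             0.2 * cos(b) + 0i)
  sweep(t, 2, sqrt(colSums(Mod(t)^2)), "/")
}

#' Build a synthetic retinal phantom
#'
#' Constructs ground truth for one simulated eye: ILM/RPE boundary depth
#' profiles with a foveal pit, a melanin mixture-depolarization profile
#' along the RPE, lipofuscin and macular-pigment profiles for the
#' autofluorescence scenes, and the intact ellipsoid-zone extent.  The
#' default geometry mirrors a 6 x 6 mm macular raster of 1024 A-scans x
#' 256 B-scans with 4.2-um axial pixels.
#'
#' Melanin presets:
#' \describe{
#'   \item{monotone}{`floor + (peak - floor) * exp(-|d| / decay)` with `d`
#'     the signed distance from the fovea in mm: peaks at the fovea and is
#'     non-increasing away from it.}
#'   \item{flat}{constant `melaninFlat` at every column.}
#'   \item{step}{`stepLow` temporal of `stepCol`, `stepHigh` from it on.}
#' }
#'
#' @param nCols,nRows,nBscans raster dimensions (defaults 1024, 512, 256).
#' @param widthMm physical scan width (default 6 mm).
#' @param pixelDxUm transverse pitch; defaults to `widthMm * 1000 / nCols`.
#' @param pixelDzUm axial pitch (default 4.2 um).
#' @param foveaCol,foveaBscan fovea location (defaults: raster center).
#' @param eye "OD" or "OS".
#' @param melaninPreset "monotone", "flat" or "step".
#' @param melaninPeak,melaninFloor,melaninDecayMm monotone-preset
#'   parameters (defaults 0.20, 0.08, 1.6 mm: the closed-form entropies at
#'   the fovea and at 2 mm are then about 0.42 and 0.28, the scale reported
#'   for eyes with retinitis pigmentosa).
#' @param melaninFlat flat-preset value (default 0.3).
#' @param stepCol,stepLow,stepHigh step-preset parameters.
#' @param macularPigmentPeak foveal macular-pigment attenuation peak in
#'   [0, 1] (default 0.8; 1 extinguishes SW-AF at the fovea).
#' @param crtUm central retinal thickness at the fovea (default 225 um).
#' @param periphUm peripheral retinal thickness (default 300 um).
#' @param ezHalfwidthUm intact-EZ half width (default 1000 um).
#' @param rpeBandPx thickness of the depolarizing RPE band (default 8 px,
#'   about 34 um).
#' @param seed integer; phantoms are deterministic functions of their
#'   arguments, the seed is recorded for provenance only.
#' @return A [RetinalPhantom-class] object.
#' @examples
#' ph <- makePhantom(nCols = 256, nRows = 160, nBscans = 1)
#' max(melaninProfile(ph)) == melaninProfile(ph)[ph@foveaCol]
#' @export
makePhantom <- function(nCols = 1024L, nRows = 512L, nBscans = 256L,
                        widthMm = 6, pixelDxUm = widthMm * 1000 / nCols,
                        pixelDzUm = 4.2,
                        foveaCol = as.integer(round((nCols + 1) / 2)),
                        foveaBscan = as.integer(round((nBscans + 1) / 2)),
                        eye = c("OD", "OS"),
                        melaninPreset = c("monotone", "flat", "step"),
                        melaninPeak = 0.20, melaninFloor = 0.08,
                        melaninDecayMm = 1.6, melaninFlat = 0.3,
                        stepCol = foveaCol, stepLow = 0.2, stepHigh = 0.6,
                        macularPigmentPeak = 0.8, crtUm = 225, periphUm = 300,
                        ezHalfwidthUm = 1000, rpeBandPx = 8L,
                        seed = 1L) {
  eye <- match.arg(eye)
  melaninPreset <- match.arg(melaninPreset)
  nCols <- as.integer(nCols); nRows <- as.integer(nRows)
  nBscans <- as.integer(nBscans)
  cols <- seq_len(nCols)
  dMm <- (cols - foveaCol) * pixelDxUm / 1000

  melanin <- switch(melaninPreset,
    monotone = melaninFloor +
      (melaninPeak - melaninFloor) * exp(-abs(dMm) / melaninDecayMm),
    flat = rep(melaninFlat, nCols),
    step = ifelse(cols < stepCol, stepLow, stepHigh))

  lipofuscin <- 0.8 - 0.25 * pmax(0, abs(dMm) * 1000 - ezHalfwidthUm) / 3000
  lipofuscin <- pmin(pmax(lipofuscin, 0), 1)
  macularPigment <- macularPigmentPeak * exp(-dMm^2 / (2 * 0.35^2))

  rpeZ <- round(0.65 * nRows) - 3 * (dMm / (widthMm / 2))^2
  thicknessUm <- periphUm - (periphUm - crtUm) * exp(-dMm^2 / (2 * 0.45^2))
  ilmZ <- rpeZ - thicknessUm / pixelDzUm
  if (any(ilmZ < 1) || any(ilmZ >= rpeZ) ||
      any(rpeZ + rpeBandPx - 1 > nRows))
    stop("invalid phantom geometry: boundaries do not fit in nRows")

  new("RetinalPhantom",
      nCols = nCols, nRows = nRows, nBscans = nBscans,
      widthMm = widthMm, pixelDxUm = pixelDxUm, pixelDzUm = pixelDzUm,
      foveaCol = as.integer(foveaCol), foveaBscan = as.integer(foveaBscan),
      ilmZ = ilmZ, rpeZ = rpeZ, rpeBandPx = as.integer(rpeBandPx),
      melanin = melanin, lipofuscin = lipofuscin,
      macularPigment = macularPigment,
      ezHalfwidthUm = ezHalfwidthUm, eye = eye)
}

#' Closed-form expected entropy of the depolarization mixture
#'
#' For the two-component mixture in which a pixel's vectorised Jones matrix
#' is, with probability `m`, an isotropic (Haar-random) unit vector in
#' C^4 and otherwise a fixed target vector, the ensemble coherency is
#' `(1 - m) t0 t0^H + (m / 4) I`, whose eigenvalue spectrum is
#' `{(1 - m) + m/4, m/4, m/4, m/4}`.  This returns its base-4 entropy,
#' which increases strictly from 0 (at `m = 0`) to 1 (at `m = 1`) and is
#' the analytic ground truth against which estimated entropy maps are
#' validated.
#'
#' @param m mixture parameter(s) in [0, 1] (vectorised).
#' @return Expected entropy in [0, 1].
#' @examples
#' closedFormEntropy(c(0, 0.5, 1))  # 0, ~0.7744, 1
#' @export
closedFormEntropy <- function(m) {
  if (any(m < 0 | m > 1) || anyNA(m))
    stop("mixture parameter m must lie in [0, 1]")
  vapply(m, function(mi) {
    lam <- c((1 - mi) + mi / 4, rep(mi / 4, 3))
    p <- lam[lam > 0]
    -sum(p * log(p)) / log(4)
  }, numeric(1))
}

# draw n Haar-random unit vectors in C^4 (columns)
.haarVectors <- function(n) {
  z <- matrix(complex(real = stats::rnorm(4 * n),
                      imaginary = stats::rnorm(4 * n)), nrow = 4)
  sweep(z, 2, sqrt(colSums(Mod(z)^2)), "/")
}

#' Render a Jones-matrix volume from a phantom
#'
#' Simulates the PS-OCT measurement of a phantom under the two-component
#' depolarization mixture model.  At each pixel of the RPE band the
#' vectorised Jones matrix is, with probability `m(col)`, a Haar-random
#' unit vector in C^4, and otherwise a fixed column-dependent target
#' vector; inner retinal tissue uses a background mixture value, the
#' choroid a moderate one, and the vitreous is signal-free.  When speckle
#' is enabled every pixel's vector is multiplied by an independent circular
#' complex Gaussian amplitude (Rayleigh modulus); additive circular complex
#' Gaussian noise is applied to every Jones element at the requested SNR,
#' defined relative to the mean RPE signal power summed over the four
#' elements (noise power per element `sigma2 = 10^(-snrDb/10) / 4`).
#'
#' The ensemble coherency of the RPE band is
#' `(1 - m) t0 t0^H + (m / 4) I` up to amplitude scaling, so estimated
#' entropies can be compared with [closedFormEntropy].
#'
#' @param phantom a [RetinalPhantom-class].
#' @param noise a [NoiseSpec-class]; rendering is bit-reproducible for a
#'   fixed seed.
#' @param bscans integer vector of B-scan indices to render (default: all).
#' @param backgroundM mixture value of non-RPE retinal tissue (default
#'   0.05).
#' @param tissuePower,choroidPower,choroidM signal power of inner retina
#'   and choroid relative to the RPE, and the choroid mixture value.
#' @return A [JonesVolume-class].
#' @examples
#' ph <- makePhantom(nCols = 64, nRows = 120, nBscans = 1)
#' vol <- renderJonesVolume(ph, NoiseSpec(seed = 1), bscans = 1L)
#' dim(jonesArray(vol))
#' @export
renderJonesVolume <- function(phantom, noise = NoiseSpec(),
                              bscans = seq_len(phantom@nBscans),
                              backgroundM = 0.05,
                              tissuePower = 0.3, choroidPower = 0.4,
                              choroidM = 0.35) {
  stopifnot(is(phantom, "RetinalPhantom"), is(noise, "NoiseSpec"))
  validObject(phantom)
  nz <- phantom@nRows; nx <- phantom@nCols
  sigma2 <- if (is.finite(noise@snrDb)) 10^(-noise@snrDb / 10) / 4 else 0

  ilm <- round(phantom@ilmZ)
  rpe0 <- round(phantom@rpeZ)
  rpe1 <- rpe0 + phantom@rpeBandPx - 1L
  zidx <- seq_len(nz)

  # per-column maps (identical for every B-scan; melanin varies with
  # column only, which keeps the foveal B-scan faithful to the profile)
  mMap <- matrix(0, nz, nx)
  pMap <- matrix(0, nz, nx)
  for (col in seq_len(nx)) {
    tis <- zidx >= ilm[col] & zidx < rpe0[col]
    band <- zidx >= rpe0[col] & zidx <= rpe1[col]
    chor <- zidx > rpe1[col]
    mMap[tis, col] <- backgroundM
    pMap[tis, col] <- tissuePower
    mMap[band, col] <- phantom@melanin[col]
    pMap[band, col] <- 1
    mMap[chor, col] <- choroidM
    pMap[chor, col] <- choroidPower
  }

  t0 <- .targetVector(seq_len(nx), nx)             # 4 x nx, RPE/choroid
  t0t <- .targetVector(seq_len(nx), nx, phase = 1) # 4 x nx, inner tissue

  set.seed(noise@seed)
  out <- array(complex(real = 0, imaginary = 0), dim = c(nz, nx, 4,
                                                         length(bscans)))
  npx <- nz * nx
  for (bi in seq_along(bscans)) {
    T <- array(complex(real = 0, imaginary = 0), dim = c(nz, nx, 4))
    isTis <- pMap == tissuePower & mMap == backgroundM
    for (k in 1:4) {
      base <- matrix(t0[k, ], nz, nx, byrow = TRUE)
      base[isTis] <- matrix(t0t[k, ], nz, nx, byrow = TRUE)[isTis]
      T[, , k] <- base
    }
    depol <- matrix(stats::runif(npx) < mMap, nz, nx) & pMap > 0
    nd <- sum(depol)
    if (nd > 0) {
      h <- .haarVectors(nd)
      for (k in 1:4) {
        plane <- T[, , k]
        plane[depol] <- h[k, ]
        T[, , k] <- plane
      }
    }
    amp <- if (noise@speckle) {
      matrix(complex(real = stats::rnorm(npx, sd = sqrt(0.5)),
                     imaginary = stats::rnorm(npx, sd = sqrt(0.5))),
             nz, nx)
    } else {
      matrix(1 + 0i, nz, nx)
    }
    amp <- amp * sqrt(pMap)
    for (k in 1:4) {
      plane <- T[, , k] * amp
      if (sigma2 > 0)
        plane <- plane +
          complex(real = stats::rnorm(npx, sd = sqrt(sigma2 / 2)),
                  imaginary = stats::rnorm(npx, sd = sqrt(sigma2 / 2)))
      T[, , k] <- plane
    }
    out[, , , bi] <- T
  }

  new("JonesVolume", jones = out,
      pixelDxUm = phantom@pixelDxUm, pixelDzUm = phantom@pixelDzUm,
      widthMm = phantom@widthMm, eye = phantom@eye,
      foveaCol = phantom@foveaCol,
      foveaBscan = as.integer(match(phantom@foveaBscan, bscans)))
}

# interpolate a per-column phantom profile at radius r (mm) from the fovea
.radialLookup <- function(phantom, values, rMm) {
  colEq <- phantom@foveaCol + rMm * 1000 / phantom@pixelDxUm
  stats::approx(seq_len(phantom@nCols), values, xout = colEq,
                rule = 2)$y
}

#' Render a synthetic autofluorescence scene
#'
#' Evaluates an analytic radial AF scene for the phantom and stores it as
#' it would be measured by a fundus camera whose pixel grid is related to
#' the OCT en-face frame by a known affine transform (a device-geometry
#' base mapping composed with a rotation/scale/translation misalignment).
#' NIR-AF intensity is proportional to the melanin profile plus a constant
#' choroidal background; SW-AF is proportional to
#' `lipofuscin * (1 - macularPigment)` with an optional annular
#' hyperautofluorescent ring multiplier at the EZ border radius.
#'
#' @param phantom a [RetinalPhantom-class].
#' @param modality "SW" or "NIR".
#' @param misalignment list with elements `rotationDeg`, `scale`,
#'   `translatePx` (length 2) describing the deviation from the device
#'   geometry; defaults to none.
#' @param noise a [NoiseSpec-class]; `snrDb` sets the additive image noise
#'   relative to the RMS scene intensity, `seed` the realisation.
#' @param sizePx AF image size (default 768).
#' @param nLandmarks number of landmark pairs to emit (>= 4; default 6).
#' @param landmarkJitterPx Gaussian jitter applied to the AF-side landmark
#'   coordinates (default 0: exact pairs).
#' @param ring enable the hyperautofluorescent ring on SW scenes (default
#'   `TRUE`).
#' @param ringAmp,ringSigmaMm ring multiplier amplitude and radial width.
#' @param choroidBg,nirGain NIR background and gain.
#' @return An [AFScene-class].
#' @export
renderAFScene <- function(phantom, modality = c("NIR", "SW"),
                          misalignment = list(rotationDeg = 0, scale = 1,
                                              translatePx = c(0, 0)),
                          noise = NoiseSpec(snrDb = 30),
                          sizePx = 768L, nLandmarks = 6L,
                          landmarkJitterPx = 0,
                          ring = TRUE, ringAmp = 0.8, ringSigmaMm = 0.15,
                          choroidBg = 0.15, nirGain = 1) {
  modality <- match.arg(modality)
  stopifnot(is(phantom, "RetinalPhantom"))
  if (nLandmarks < 4L)
    stop("at least 4 landmark pairs are required")

  # device geometry: the widthMm OCT raster (about 20 degrees) occupies
  # 2/3 of the 30-degree AF field, centred
  span <- sizePx * 2 / 3
  sx <- span / phantom@nCols
  sy <- span / phantom@nBscans
  A0 <- diag(c(sx, sy))
  ctrAf <- c((sizePx + 1) / 2, (sizePx + 1) / 2)
  ctrEn <- c((phantom@nCols + 1) / 2, (phantom@nBscans + 1) / 2)
  b0 <- ctrAf - A0 %*% ctrEn

  th <- misalignment$rotationDeg * pi / 180
  M <- misalignment$scale * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  A <- M %*% A0
  b <- as.numeric(M %*% (b0 - ctrAf) + ctrAf + misalignment$translatePx)
  trueT <- AffineTransform2D(A = A, b = b)

  # evaluate the scene at every AF pixel by inverse-mapping to the
  # en-face frame and computing the radius from the fovea in mm
  Ainv <- solve(A)
  u <- rep(seq_len(sizePx), each = sizePx)   # x (image column)
  v <- rep(seq_len(sizePx), times = sizePx)  # y (image row)
  px <- Ainv[1, 1] * (u - b[1]) + Ainv[1, 2] * (v - b[2])
  py <- Ainv[2, 1] * (u - b[1]) + Ainv[2, 2] * (v - b[2])
  dyMm <- phantom@widthMm / phantom@nBscans
  rMm <- sqrt(((px - phantom@foveaCol) * phantom@pixelDxUm / 1000)^2 +
              ((py - phantom@foveaBscan) * dyMm)^2)

  if (modality == "NIR") {
    img <- choroidBg + nirGain * .radialLookup(phantom, phantom@melanin, rMm)
  } else {
    img <- .radialLookup(phantom, phantom@lipofuscin, rMm) *
      (1 - .radialLookup(phantom, phantom@macularPigment, rMm))
    if (ring) {
      rEz <- phantom@ezHalfwidthUm / 1000
      img <- img * (1 + ringAmp * exp(-(rMm - rEz)^2 / (2 * ringSigmaMm^2)))
    }
  }
  img <- matrix(img, sizePx, sizePx)  # rows = y, cols = x

  set.seed(noise@seed)
  if (is.finite(noise@snrDb)) {
    sdNoise <- sqrt(mean(img^2)) * 10^(-noise@snrDb / 20)
    img <- pmax(img + matrix(stats::rnorm(length(img), sd = sdNoise),
                             nrow(img)), 0)
  }

  srcX <- phantom@nCols * stats::runif(nLandmarks, 0.1, 0.9)
  srcY <- phantom@nBscans * stats::runif(nLandmarks, 0.1, 0.9)
  dst <- A %*% rbind(srcX, srcY) + b
  if (landmarkJitterPx > 0)
    dst <- dst + matrix(stats::rnorm(2 * nLandmarks,
                                     sd = landmarkJitterPx), 2)
  lm <- data.frame(x_enface = srcX, y_enface = srcY,
                   x_af = dst[1, ], y_af = dst[2, ])

  new("AFScene", image = img, modality = modality, trueTransform = trueT,
      landmarks = lm)
}

#' Generate a synthetic cohort
#'
#' Draws `nEyes` phantoms with per-eye melanin, EZ and thickness parameters
#' and assembles the ground-truth cohort table (one row per eye with the
#' demographic and morphometric schema used throughout the package).
#' Section entropies are the closed-form values of each eye's melanin
#' profile at the fovea and at +/- 2 mm; ages span 24-68 years, EZ widths
#' 650-3890 um and CRT 182-271 um, the ranges observed in the reference
#' cohort of 12 eyes with retinitis pigmentosa.
#'
#' @param nEyes number of eyes (>= 1).
#' @param seed integer seed; tables and phantoms are deterministic per
#'   seed.
#' @param nCols,nRows,nBscans raster dimensions passed to [makePhantom]
#'   (defaults sized for simulation studies).
#' @return A list with elements `cohort` (data.frame) and `phantoms`
#'   (list of [RetinalPhantom-class]).
#' @examples
#' cs <- makeCohort(3, seed = 7)
#' nrow(cs$cohort)
#' @export
makeCohort <- function(nEyes, seed = 1L, nCols = 1024L, nRows = 192L,
                       nBscans = 64L) {
  stopifnot(nEyes >= 1)
  set.seed(seed)
  ages <- sample(24:68, nEyes, replace = TRUE)
  sexes <- sample(c("F", "M"), nEyes, replace = TRUE, prob = c(2 / 3, 1 / 3))
  eyes <- sample(c("OD", "OS"), nEyes, replace = TRUE, prob = c(0.9, 0.1))
  genes <- sample(c("EYS", "USH2A", NA), nEyes, replace = TRUE)
  lenses <- sample(c("phakia", "pseudophakia"), nEyes, replace = TRUE,
                   prob = c(0.9, 0.1))
  bcva <- sample(c(0.7, 0.9, 1.0, 1.2, 1.5), nEyes, replace = TRUE)
  ezW <- stats::runif(nEyes, 650, 3890)
  crt <- stats::runif(nEyes, 182, 271)
  peak <- stats::runif(nEyes, 0.14, 0.30)
  floorM <- stats::runif(nEyes, 0.04, 0.10)
  decay <- stats::runif(nEyes, 1.2, 2.2)

  phantoms <- vector("list", nEyes)
  ef <- et <- en <- numeric(nEyes)
  for (i in seq_len(nEyes)) {
    ph <- makePhantom(nCols = nCols, nRows = nRows, nBscans = nBscans,
                      eye = eyes[i], melaninPeak = peak[i],
                      melaninFloor = floorM[i], melaninDecayMm = decay[i],
                      crtUm = crt[i], ezHalfwidthUm = ezW[i] / 2)
    phantoms[[i]] <- ph
    mAt <- function(dMm) {
      col <- ph@foveaCol + dMm * 1000 / ph@pixelDxUm
      stats::approx(seq_len(ph@nCols), ph@melanin, xout = col, rule = 2)$y
    }
    ef[i] <- closedFormEntropy(mAt(0))
    et[i] <- closedFormEntropy(mAt(-2))
    en[i] <- closedFormEntropy(mAt(2))
  }
  cohort <- data.frame(
    patient_id = seq_len(nEyes), age = ages, sex = sexes, eye = eyes,
    gene = genes, lens = lenses, bcva_decimal = bcva,
    entropy_fovea = ef, entropy_temporal = et, entropy_nasal = en,
    ez_width_um = ezW, crt_um = crt, stringsAsFactors = FALSE)
  list(cohort = cohort, phantoms = phantoms)
}
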