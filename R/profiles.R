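#' @include AllGenerics.R
NULL

#' Entropy along a segmented RPE line
#'
#' For each column of the trace, averages the entropy map over a 6-pixel
#' axial window (about 25 um at 4.2-um pixels) about the segmentation line:
#' the line's depth is rounded half-up, and the window spans 3 pixels above
#' and 2 below the rounded line plus the line pixel.  The window is clipped
#' at the image borders and invalid (`NA`) pixels are excluded from the
#' mean.
#'
#' @param map an [EntropyMap-class].
#' @param trace a [SegTrace-class] with boundary "RPE", defined on columns
#'   of the map.
#' @param windowPx axial window size in pixels (default 6).
#' @return Named numeric vector of per-column mean entropy (names are
#'   column indices); `NA` where no valid pixel falls in the window.
#' @export
rpeLineEntropy <- function(map, trace, windowPx = 6L) {
  stopifnot(is(map, "EntropyMap"), is(trace, "SegTrace"))
  if (trace@boundary != "RPE")
    stop("trace boundary must be 'RPE'")
  v <- map@values
  nz <- nrow(v); nx <- ncol(v)
  if (any(trace@cols < 1L | trace@cols > nx))
    stop("trace columns outside the map")
  zc <- floor(trace@z + 0.5)  # round half-up
  above <- ceiling((windowPx - 1) / 2)   # 3 for a 6-px window
  below <- windowPx - 1L - above         # 2
  if (all(zc + below < 1 | zc - above > nz))
    stop("trace entirely outside the image")
  out <- rep(NA_real_, length(trace@cols))
  for (i in seq_along(trace@cols)) {
    rows <- max(1L, zc[i] - above):min(nz, zc[i] + below)
    if (rows[1] > nz || rows[length(rows)] < 1) next
    px <- v[rows, trace@cols[i]]
    if (any(!is.na(px))) out[i] <- mean(px, na.rm = TRUE)
  }
  names(out) <- trace@cols
  out
}

#' Bin per-column values into 0.25-mm sections
#'
#' Converts column indices to signed distances from the fovea
#' (`(col - foveaCol) * pixelDxUm / 1000` mm), assigns each column to a
#' contiguous section of width `binWidthMm` (the foveal section covers
#' offsets in `[-binWidthMm/2, +binWidthMm/2)`), and averages the values in
#' each section (unweighted).  Edge sections covered by fewer than half the
#' nominal column count are dropped, as partial sections are not reported.
#'
#' @param values numeric vector of per-column values (`NA` allowed).
#' @param foveaCol fovea column index.
#' @param pixelDxUm transverse pixel pitch (um).
#' @param cols column indices corresponding to `values` (default
#'   `seq_along(values)`).
#' @param binWidthMm section width (default 0.25 mm).
#' @param eye "OD" or "OS", carried into the profile.
#' @return An unoriented [SectionProfile-class].
#' @export
binSections <- function(values, foveaCol, pixelDxUm,
                        cols = seq_along(values), binWidthMm = 0.25,
                        eye = "OD") {
  stopifnot(length(cols) == length(values))
  if (foveaCol < min(cols) || foveaCol > max(cols))
    stop("foveaCol outside the column range")
  offMm <- (cols - foveaCol) * pixelDxUm / 1000
  idx <- floor(offMm / binWidthMm + 0.5)
  nominal <- binWidthMm * 1000 / pixelDxUm
  keep <- table(idx) >= nominal / 2
  kept <- as.integer(names(keep))[keep]
  kept <- sort(kept)
  if (length(kept) == 0L) stop("no section has sufficient coverage")
  # kept bins are contiguous by construction (only edges are partial)
  meanV <- vapply(kept, function(k)
    mean(values[idx == k], na.rm = TRUE), numeric(1))
  meanV[is.nan(meanV)] <- NA_real_
  nPx <- vapply(kept, function(k) sum(idx == k), integer(1))
  new("SectionProfile", binCenterMm = kept * binWidthMm, meanValue = meanV,
      nPixels = nPx, binWidthMm = binWidthMm, eye = eye, oriented = FALSE)
}

#' Orient a section profile temporal-negative
#'
#' Charts are displayed with the temporal side on the left (negative bin
#' centers) for every eye; profiles of left eyes (OS) are therefore
#' laterally reversed, while right eyes (OD) are unchanged.  Orientation is
#' recorded and may only be applied once.
#'
#' @param profile an unoriented [SectionProfile-class] (or [AFProfile-class]).
#' @param eye "OD" or "OS"; defaults to the profile's own eye.
#' @return The oriented profile.
#' @export
orientProfile <- function(profile, eye = profile@eye) {
  stopifnot(is(profile, "SectionProfile"))
  if (profile@oriented)
    stop("profile is already oriented")
  out <- profile
  if (eye == "OS") {
    ord <- order(-profile@binCenterMm)
    out@binCenterMm <- -profile@binCenterMm[ord]
    out@meanValue <- profile@meanValue[ord]
    out@nPixels <- profile@nPixels[ord]
  }
  out@eye <- eye
  out@oriented <- TRUE
  out
}

#' Mean value of a named section
#'
#' Returns the mean of the foveal section (bin center 0) or of the temporal
#' / nasal sections located `offsetMm` from the fovea (default 2 mm;
#' temporal is negative after orientation).
#'
#' @param profile an oriented [SectionProfile-class].
#' @param which "fovea", "temporal" or "nasal".
#' @param offsetMm distance of the temporal/nasal sections from the fovea
#'   (default 2 mm).
#' @return The section mean, or `NA` if the section was dropped at the
#'   profile edge.
#' @export
sectionValue <- function(profile, which = c("fovea", "temporal", "nasal"),
                         offsetMm = 2) {
  stopifnot(is(profile, "SectionProfile"))
  which <- match.arg(which)
  if (!profile@oriented)
    stop("profile must be oriented before section lookup")
  target <- switch(which, fovea = 0, temporal = -offsetMm, nasal = offsetMm)
  hit <- which(abs(profile@binCenterMm - target) < 1e-9)
  if (length(hit) == 0L) return(NA_real_)
  profile@meanValue[hit]
}

#' Ellipsoid-zone width from its border columns
#'
#' The EZ width is the distance between the temporal and nasal borders
#' where the EZ line disappears, corrected to the physical imaging range:
#' `(nasalCol - temporalCol) * widthMm * 1000 / nCols` um.
#'
#' @param temporalCol,nasalCol border column positions
#'   (`temporalCol < nasalCol`).
#' @param nCols A-scans per B-scan.
#' @param widthMm physical scan width (default 6 mm).
#' @return EZ width in um.
#' @examples
#' computeEZWidth(0, 1024, 1024)  # 6000
#' @export
computeEZWidth <- function(temporalCol, nasalCol, nCols, widthMm = 6) {
  if (nasalCol < temporalCol)
    stop("temporalCol must not exceed nasalCol")
  if (temporalCol < 0 || nasalCol > nCols)
    stop("border columns out of range")
  (nasalCol - temporalCol) * widthMm * 1000 / nCols
}

#' Central retinal thickness at the fovea
#'
#' Distance from the vitreoretinal interface (ILM) to the inner border of
#' the RPE at the foveal column, converted to um by the axial pixel pitch.
#'
#' @param ilm,rpe [SegTrace-class] objects (ILM and inner-RPE boundaries)
#'   defined at `foveaCol`.
#' @param foveaCol fovea column index.
#' @param pixelDzUm axial pixel pitch (default 4.2 um).
#' @return CRT in um.
#' @export
computeCRT <- function(ilm, rpe, foveaCol, pixelDzUm = 4.2) {
  stopifnot(is(ilm, "SegTrace"), is(rpe, "SegTrace"))
  zi <- ilm@z[match(foveaCol, ilm@cols)]
  zr <- rpe@z[match(foveaCol, rpe@cols)]
  if (is.na(zi) || is.na(zr))
    stop("both traces must be defined at foveaCol")
  if (zr < zi)
    stop("RPE must lie below the ILM")
  (zr - zi) * pixelDzUm
}
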