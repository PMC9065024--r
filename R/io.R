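#' @include AllGenerics.R
NULL

#' Read / write segmentation traces
#'
#' CSV with header `col,z` (1-based column indices, depth in pixels).
#'
#' @param path CSV file path.
#' @param trace a [SegTrace-class].
#' @param boundary,source metadata for the trace being read.
#' @return `readTrace` returns a [SegTrace-class]; `writeTrace` the path,
#'   invisibly.
#' @export
readTrace <- function(path, boundary = "RPE", source = "manual") {
  df <- utils::read.csv(path)
  if (!all(c("col", "z") %in% names(df)))
    stop("trace CSV must have columns 'col' and 'z': ", path)
  SegTrace(df$col, df$z, boundary = boundary, source = source)
}

#' @rdname readTrace
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "SegTrace"))
  utils::write.csv(data.frame(col = trace@cols, z = trace@z), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write section profiles
#'
#' CSV with columns `bin_center_mm,mean,n_pixels` plus the metadata
#' columns `eye` and `oriented` (and `modality`, `normalized` for AF
#' profiles).  Round-trips are identity: reading a written profile
#' reconstructs an equal object.
#'
#' @param path CSV file path.
#' @param profile a [SectionProfile-class] or [AFProfile-class].
#' @return `readProfile` returns the profile; `writeProfile` the path,
#'   invisibly.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "SectionProfile"))
  df <- data.frame(bin_center_mm = profile@binCenterMm,
                   mean = profile@meanValue,
                   n_pixels = profile@nPixels,
                   eye = profile@eye,
                   oriented = profile@oriented)
  if (is(profile, "AFProfile")) {
    df$modality <- profile@modality
    df$normalized <- profile@normalized
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  df <- utils::read.csv(path)
  need <- c("bin_center_mm", "mean", "n_pixels", "eye", "oriented")
  if (!all(need %in% names(df)))
    stop("profile CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if ("modality" %in% names(df)) {
    new("AFProfile", binCenterMm = df$bin_center_mm, meanValue = df$mean,
        nPixels = as.integer(df$n_pixels), binWidthMm = 0.25,
        eye = df$eye[1], oriented = df$oriented[1],
        modality = df$modality[1], normalized = df$normalized[1])
  } else {
    new("SectionProfile", binCenterMm = df$bin_center_mm,
        meanValue = df$mean, nPixels = as.integer(df$n_pixels),
        binWidthMm = 0.25, eye = df$eye[1], oriented = df$oriented[1])
  }
}

#' Read / write landmark pairs
#'
#' CSV with header `x_enface,y_enface,x_af,y_af`.
#'
#' @param path CSV file path.
#' @param landmarks data.frame of matched points.
#' @return `readLandmarks` returns the data.frame; `writeLandmarks` the
#'   path, invisibly.
#' @export
readLandmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_enface", "y_enface", "x_af", "y_af")
  if (!all(need %in% names(df)))
    stop("landmark CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' @rdname readLandmarks
#' @export
writeLandmarks <- function(landmarks, path) {
  utils::write.csv(landmarks, path, row.names = FALSE)
  invisible(path)
}

#' Read / write cohort tables
#'
#' CSV with the one-row-per-eye cohort schema (see [validateCohort]).
#'
#' @param path CSV file path.
#' @param cohort a cohort data.frame.
#' @return `readCohort` returns the validated data.frame; `writeCohort`
#'   the path, invisibly.
#' @export
readCohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateCohort(df)
  df
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, path) {
  validateCohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Packaged reference cohort
#'
#' The demographic and clinical table of the reference case series: 12
#' eyes of 12 patients with retinitis pigmentosa and a hyperautofluorescent
#' ring, with per-eye section entropies, EZ width and CRT.
#'
#' @return The cohort data.frame.
#' @examples
#' summarizeCohort(referenceCohort())
#' @export
referenceCohort <- function() {
  path <- system.file("extdata", "reference_cohort.csv",
                      package = "rpeEntropy", mustWork = TRUE)
  readCohort(path)
}
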