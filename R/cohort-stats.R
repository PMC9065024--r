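#' @include AllGenerics.R
NULL

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties averaged).  The two-sided
#' p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` for n > 10, and an exact
#' permutation test (all n! arrangements) for n <= 10.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return A list with elements `rho`, `p` and `n`.
#' @examples
#' spearmanCorr(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
#' @export
spearmanCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n > 10L) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  } else {
    p <- cpp_spearman_perm_pvalue(rx, ry)
  }
  list(rho = rho, p = min(p, 1), n = n)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Two-sided comparison of two independent samples by average ranks.  The
#' null distribution is enumerated exactly when the combined sample size is
#' at most 12 and there are no ties; otherwise the normal approximation
#' with tie correction is used.
#'
#' @param a,b non-empty numeric vectors.
#' @return A list with elements `p`, `statistic` (Mann-Whitney U of the
#'   first sample) and `exact` (logical).
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
rankSumTest <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- !ties && (length(a) + length(b)) <= 12L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  list(p = wt$p.value, statistic = unname(wt$statistic), exact = exact)
}

#' Bonferroni correction
#'
#' `min(1, p * k)` elementwise.
#'
#' @param p vector of p-values in [0, 1].
#' @param k number of comparisons (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, k) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (k < 1) stop("k must be >= 1")
  pmin(1, p * k)
}

#' Decimal visual acuity to logMAR
#'
#' `logMAR = -log10(decimal acuity)`.
#'
#' @param va decimal acuity (> 0), vectorised.
#' @return logMAR value(s).
#' @examples
#' decimalToLogmar(1)    # 0
#' decimalToLogmar(0.7)  # ~0.155
#' @export
decimalToLogmar <- function(va) {
  if (any(va <= 0, na.rm = TRUE)) stop("decimal acuity must be > 0")
  -log10(va)
}

.cohortColumns <- c("patient_id", "age", "sex", "eye", "gene", "lens",
                    "bcva_decimal", "entropy_fovea", "entropy_temporal",
                    "entropy_nasal", "ez_width_um", "crt_um")

#' Validate a cohort table
#'
#' Checks the one-row-per-eye cohort schema: required columns present,
#' entropies in [0, 1], decimal BCVA positive.
#'
#' @param cohort a data.frame.
#' @return The cohort, invisibly; errors list the missing columns.
#' @export
validateCohort <- function(cohort) {
  missing <- setdiff(.cohortColumns, names(cohort))
  if (length(missing))
    stop("cohort is missing columns: ", paste(missing, collapse = ", "))
  ent <- unlist(cohort[c("entropy_fovea", "entropy_temporal",
                         "entropy_nasal")])
  if (any(ent < 0 | ent > 1, na.rm = TRUE))
    stop("section entropies must lie in [0, 1]")
  if (any(cohort$bcva_decimal <= 0, na.rm = TRUE))
    stop("decimal BCVA must be > 0")
  invisible(cohort)
}

#' Cohort summary statistics
#'
#' Means and sample (n-1) standard deviations of age, logMAR BCVA
#' (converted from the decimal acuities), the three section entropies, EZ
#' width and CRT.  SDs are `NA` for a single-row table.
#'
#' @param cohort a cohort data.frame (see [validateCohort]).
#' @return A data.frame with columns `variable`, `mean`, `sd`, `n`.
#' @export
summarizeCohort <- function(cohort) {
  validateCohort(cohort)
  vars <- list(
    age = cohort$age,
    logmar_bcva = decimalToLogmar(cohort$bcva_decimal),
    entropy_fovea = cohort$entropy_fovea,
    entropy_temporal = cohort$entropy_temporal,
    entropy_nasal = cohort$entropy_nasal,
    ez_width_um = cohort$ez_width_um,
    crt_um = cohort$crt_um)
  data.frame(
    variable = names(vars),
    mean = vapply(vars, function(v) mean(v, na.rm = TRUE), numeric(1)),
    sd = vapply(vars, function(v)
      if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else NA_real_,
      numeric(1)),
    n = vapply(vars, function(v) sum(!is.na(v)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise comparison of section entropies
#'
#' Wilcoxon rank-sum tests between the foveal, temporal and nasal section
#' entropies with Bonferroni correction over the k = 3 comparisons.  Both
#' raw and adjusted p-values are reported.
#'
#' @param cohort a cohort data.frame with >= 3 rows.
#' @return A data.frame with columns `comparison`, `p_raw`, `p_adjusted`.
#' @export
sectionComparison <- function(cohort) {
  validateCohort(cohort)
  if (nrow(cohort) < 3L) stop("need at least 3 eyes")
  pairs <- list(
    fovea_vs_temporal = c("entropy_fovea", "entropy_temporal"),
    fovea_vs_nasal = c("entropy_fovea", "entropy_nasal"),
    temporal_vs_nasal = c("entropy_temporal", "entropy_nasal"))
  pRaw <- vapply(pairs, function(pr)
    rankSumTest(cohort[[pr[1]]], cohort[[pr[2]]])$p, numeric(1))
  data.frame(comparison = names(pairs), p_raw = unname(pRaw),
             p_adjusted = unname(bonferroni(pRaw, length(pairs))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pooled correlation between entropy and AF profiles
#'
#' Pools (entropy, AF) section pairs over all eyes — matching sections by
#' bin center within each eye — and computes a single Spearman correlation
#' per modality.  AF profiles are expected to be per-eye min-max
#' normalized ([minmaxNormalize]) so that intensities are comparable
#' across participants.
#'
#' @param entropyProfiles list of oriented [SectionProfile-class], one per
#'   eye.
#' @param afProfiles list of oriented, normalized [AFProfile-class],
#'   matched by position.
#' @return A list with `rho`, `p` and `n` (number of pooled section
#'   pairs).
#' @export
pooledAFCorrelation <- function(entropyProfiles, afProfiles) {
  stopifnot(length(entropyProfiles) == length(afProfiles))
  ent <- numeric(0); af <- numeric(0)
  for (i in seq_along(entropyProfiles)) {
    e <- entropyProfiles[[i]]; a <- afProfiles[[i]]
    common <- intersect(round(e@binCenterMm / e@binWidthMm),
                        round(a@binCenterMm / a@binWidthMm))
    if (length(common) == 0L) next
    ei <- match(common, round(e@binCenterMm / e@binWidthMm))
    ai <- match(common, round(a@binCenterMm / a@binWidthMm))
    ent <- c(ent, e@meanValue[ei])
    af <- c(af, a@meanValue[ai])
  }
  if (length(ent) == 0L) stop("no overlapping sections between profiles")
  res <- spearmanCorr(ent, af)
  list(rho = res$rho, p = res$p, n = res$n)
}

#' Foveal entropy versus clinical findings
#'
#' Spearman correlations of the foveal section entropy with age, logMAR
#' BCVA, EZ width and CRT.
#'
#' @param cohort a cohort data.frame with >= 4 rows.
#' @return A data.frame with columns `variable`, `rho`, `p`.
#' @export
clinicalPanel <- function(cohort) {
  validateCohort(cohort)
  if (nrow(cohort) < 4L) stop("need at least 4 eyes")
  vars <- list(
    age = cohort$age,
    logmar_bcva = decimalToLogmar(cohort$bcva_decimal),
    ez_width_um = cohort$ez_width_um,
    crt_um = cohort$crt_um)
  res <- lapply(vars, function(v) spearmanCorr(cohort$entropy_fovea, v))
  data.frame(variable = names(vars),
             rho = vapply(res, `[[`, numeric(1), "rho"),
             p = vapply(res, `[[`, numeric(1), "p"),
             row.names = NULL, stringsAsFactors = FALSE)
}
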