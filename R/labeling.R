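# Regression-based label construction at the OCT date: pointwise ordinary
# least squares over the longitudinal series with non-positive slope
# enforcement, validity periods, clamping, and masked 122-value assembly.

DAYS_PER_MONTH <- 365.25 / 12

monthsBetween <- function(a, b) abs(as.numeric(as.Date(a) - as.Date(b))) / DAYS_PER_MONTH

examDates <- function(series)
  as.Date(vapply(series@exams, function(e) as.numeric(e@date), numeric(1)),
          origin = "1970-01-01")

#' Label-construction configuration
#'
#' @param validityUnitMonths months credited per test in the validity
#'   period (default 6; the period is `6 * n` months for `n` tests).
#' @param singleExamWindowMonths pairing window when only one exam exists
#'   (default 6 months before or after).
#' @param thresholdRange clamp range for point labels, dB (default 0..33).
#' @param mdRange clamp range for MD labels, dB (default -33..0).
#' @param maskMissingValue mask value marking absent data (default 1).
#' @param referenceExam which exam anchors the validity-period gap:
#'   "nearest" to the OCT date (default) or "latest" in the series.
#' @return a `LabelConfig` list.
#' @export
labelConfig <- function(validityUnitMonths = 6, singleExamWindowMonths = 6,
                        thresholdRange = c(0, 33), mdRange = c(-33, 0),
                        maskMissingValue = 1,
                        referenceExam = c("nearest", "latest")) {
  referenceExam <- match.arg(referenceExam)
  stopifnot(validityUnitMonths > 0, singleExamWindowMonths > 0,
            thresholdRange[1] < thresholdRange[2], mdRange[1] < mdRange[2])
  structure(list(validityUnitMonths = validityUnitMonths,
                 singleExamWindowMonths = singleExamWindowMonths,
                 thresholdRange = thresholdRange, mdRange = mdRange,
                 maskMissingValue = maskMissingValue,
                 referenceExam = referenceExam),
            class = "LabelConfig")
}

# Core fit shared by point and MD labels. `dates` and `values` carry only
# the observations where this quantity was recorded.
regressAtDate <- function(dates, values, octDate, range, windowMonths) {
  keep <- !is.na(values)
  dates <- as.Date(dates)[keep]
  values <- values[keep]
  n <- length(values)
  if (n == 0) return(list(value = NA_real_, source = "missing"))
  if (n == 1) {
    if (monthsBetween(dates, octDate) <= windowMonths)
      return(list(value = clampTo(values, range), source = "single_exam"))
    return(list(value = NA_real_, source = "missing"))
  }
  t <- as.numeric(dates) / 365.25          # years; shift-invariant OLS
  t0 <- as.numeric(as.Date(octDate)) / 365.25
  if (length(unique(t)) == 1) {
    # all exams on one date: no time information, fall back to the mean
    return(list(value = clampTo(mean(values), range), source = "regressed"))
  }
  slope <- stats::cov(t, values) / stats::var(t)
  if (slope > 0) {
    # learning-effect guard: glaucomatous fields do not recover; the
    # zero-slope least-squares refit is the series mean
    fit <- mean(values)
  } else {
    fit <- mean(values) + slope * (t0 - mean(t))
  }
  list(value = clampTo(fit, range), source = "regressed")
}

clampTo <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Regression label for one test point at the OCT date
#'
#' With two or more exams carrying the point, fits ordinary least squares of
#' threshold on time; positive slopes are set to zero (the refit under the
#' zero-slope constraint is the series mean) and the line is read at the OCT
#' date, clamped to the threshold range. With exactly one exam, the value is
#' used directly iff the OCT lies within the single-exam window; otherwise
#' the label is absent (`NA`).
#'
#' @param series a laterality-normalized, reliability-filtered
#'   [VFSeries-class].
#' @param pointIndex index into the exam threshold vector.
#' @param octDate OCT acquisition date.
#' @param cfg a [labelConfig()].
#' @return list with `value` (dB or `NA`) and `source`.
#' @export
pointwiseRegressionLabel <- function(series, pointIndex, octDate,
                                     cfg = labelConfig()) {
  stopifnot(is(series, "VFSeries"))
  dates <- examDates(series)
  vals <- vapply(series@exams, function(e) e@thresholds[pointIndex],
                 numeric(1))
  regressAtDate(dates, vals, octDate, cfg$thresholdRange,
                cfg$singleExamWindowMonths)
}

#' Validity-period check for pairing a series with an OCT
#'
#' The validity period is `validityUnitMonths * n` months for a series of
#' `n` tests; the pair passes iff the gap between the OCT date and the
#' reference exam (nearest to the OCT by default) does not exceed it.
#'
#' @param series a [VFSeries-class].
#' @param octDate OCT acquisition date.
#' @param cfg a [labelConfig()].
#' @return logical.
#' @export
validityPeriodCheck <- function(series, octDate, cfg = labelConfig()) {
  if (!is(series, "VFSeries") || length(series@exams) == 0) return(FALSE)
  d <- examDates(series)
  ref <- switch(cfg$referenceExam,
                nearest = d[which.min(abs(as.numeric(d - as.Date(octDate))))],
                latest = max(d))
  monthsBetween(ref, octDate) <= cfg$validityUnitMonths * length(series@exams)
}

blockLabels <- function(series, pointIndices, octDate, cfg, grid) {
  nlab <- length(pointIndices) + 1L
  if (is.null(series) || !validityPeriodCheck(series, octDate, cfg)) {
    return(list(labels = rep(0, nlab), mask = rep(1, nlab),
                source = "missing"))
  }
  fits <- lapply(pointIndices, function(i)
    pointwiseRegressionLabel(series, i, octDate, cfg))
  mdDates <- examDates(series)
  mdVals <- vapply(series@exams, function(e) e@md, numeric(1))
  mdFit <- regressAtDate(mdDates, mdVals, octDate, cfg$mdRange,
                         cfg$singleExamWindowMonths)
  vals <- c(vapply(fits, `[[`, numeric(1), "value"), mdFit$value)
  mask <- as.numeric(is.na(vals)) * cfg$maskMissingValue
  vals[is.na(vals)] <- 0  # inert sentinel behind the mask
  src <- c(vapply(fits, `[[`, character(1), "source"), mdFit$source)
  source <- if (all(src == "missing")) "missing"
  else if (any(src == "regressed")) "regressed" else "single_exam"
  list(labels = vals, mask = mask, source = source)
}

#' Assemble the masked 122-value paired sample
#'
#' Builds per-point regression labels and the MD label for the 24-2 and
#' 10-2 series of one eye at the OCT date and concatenates them in the
#' fixed ordering of [labelLayout()]. A block whose series is absent or
#' fails the validity period is wholly masked (53 or 69 entries). An OCT
#' with neither block usable is rejected.
#'
#' @param series24,series10 laterality-normalized [VFSeries-class] for the
#'   24-2 and 10-2 patterns, or `NULL` when never tested.
#' @param octDate OCT acquisition date.
#' @param volumeRef identifier of the paired volume.
#' @param patientId,eyeId identifiers.
#' @param cfg a [labelConfig()].
#' @return a [PairedSample-class].
#' @export
assemblePairedSample <- function(series24, series10, octDate, volumeRef,
                                 patientId, eyeId, cfg = labelConfig()) {
  lay <- labelLayout()
  b24 <- blockLabels(series24, lay$points24, octDate, cfg, buildGrid("24-2"))
  b10 <- blockLabels(series10, seq_len(68L), octDate, cfg, buildGrid("10-2"))
  if (b24$source == "missing" && b10$source == "missing")
    stop("no usable visual-field data for this OCT")
  new("PairedSample", patientId = as.character(patientId),
      eyeId = as.character(eyeId), octDate = as.Date(octDate),
      volumeRef = as.character(volumeRef),
      labels = c(b24$labels, b10$labels), mask = c(b24$mask, b10$mask),
      provenance = c(p24 = b24$source, p10 = b10$source))
}
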