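#' @import methods
#' @importFrom stats coef cor cor.test lm median pnorm rbinom rnorm runif sd var wilcox.test
#' @importFrom utils combn head read.csv write.csv
NULL

PD_LEVELS <- c("ns", "p<5%", "p<2%", "p<1%", "p<0.5%")
GHT_LEVELS <- c("within_normal", "borderline", "outside_normal")
VF_PATTERNS <- c("24-2", "10-2", "30-2")

#' VFGrid: test-point geometry of one Humphrey pattern
#'
#' Holds the ordered test-point coordinates of a 24-2, 30-2 or 10-2 pattern in
#' the right-eye (OD) frame (x > 0 temporal, y > 0 superior, degrees), the
#' indices of the two physiologic blind-spot points (24-2/30-2 only) and the
#' row assignment of every point (rows ordered superior to inferior).
#'
#' Point order is deterministic: rows superior to inferior, and within a row
#' nasal to temporal (ascending x in the OD frame).
#'
#' @slot pattern character, one of "24-2", "10-2", "30-2".
#' @slot coords two-column numeric matrix of (x, y) in degrees, OD frame.
#' @slot blindSpot integer indices of the blind-spot points (may be empty).
#' @slot row integer row index per point, 1 = most superior.
#' @seealso [buildGrid()]
#' @export
setClass("VFGrid",
  representation(pattern = "character", coords = "matrix",
                 blindSpot = "integer", row = "integer"))

setValidity("VFGrid", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (!object@pattern %in% VF_PATTERNS)
    msg <- c(msg, "unknown pattern")
  expect_n <- c("24-2" = 54L, "10-2" = 68L, "30-2" = 76L)[object@pattern]
  if (!is.na(expect_n) && n != expect_n)
    msg <- c(msg, sprintf("pattern %s must have %d points, has %d",
                          object@pattern, expect_n, n))
  if (length(object@row) != n) msg <- c(msg, "row length mismatch")
  # every pattern is symmetric under y -> -y
  key <- paste(object@coords[, 1], object@coords[, 2])
  if (!setequal(key, paste(object@coords[, 1], -object@coords[, 2])))
    msg <- c(msg, "grid is not symmetric under vertical mirroring")
  if (object@pattern %in% c("24-2", "30-2")) {
    bs <- object@coords[object@blindSpot, , drop = FALSE]
    if (!setequal(paste(bs[, 1], bs[, 2]), c("15 3", "15 -3")))
      msg <- c(msg, "blind spot must be the points (15, +-3)")
  }
  if (length(msg)) msg else TRUE
})

#' VFExam: one automated perimetry test
#'
#' One Humphrey visual-field examination: per-point sensitivity thresholds
#' (dB, indexed by the native-frame grid order of its laterality), the
#' device summary indices and optional probability maps.
#'
#' @slot patientId,eyeId identifiers.
#' @slot laterality "OD" or "OS"; "OD" also tags exams already mapped into
#'   the OD frame by [normalizeLaterality()].
#' @slot date exam date (`Date`).
#' @slot pattern grid pattern of the test.
#' @slot thresholds numeric vector of dB thresholds, `NA` allowed.
#' @slot md mean deviation (dB).
#' @slot fpRate,fnRate,flRate false-positive, false-negative and
#'   fixation-loss rates as fractions in \[0, 1\] (`NA_real_` if unrecorded).
#' @slot pdProb optional per-point pattern-deviation probability categories
#'   (`"ns"`, `"p<5%"`, `"p<2%"`, `"p<1%"`, `"p<0.5%"`); length 0 if absent.
#' @slot psdProb optional PSD probability category (length 0 or 1).
#' @slot ght optional glaucoma hemifield test result (length 0 or 1).
#' @export
setClass("VFExam",
  representation(patientId = "character", eyeId = "character",
                 laterality = "character", date = "Date",
                 pattern = "character", thresholds = "numeric",
                 md = "numeric", fpRate = "numeric", fnRate = "numeric",
                 flRate = "numeric", pdProb = "character",
                 psdProb = "character", ght = "character"))

setValidity("VFExam", function(object) {
  msg <- character()
  if (!object@laterality %in% c("OD", "OS")) msg <- c(msg, "laterality must be OD or OS")
  if (!object@pattern %in% VF_PATTERNS) msg <- c(msg, "unknown pattern")
  th <- object@thresholds
  if (any(th < 0 | th > 50, na.rm = TRUE))
    msg <- c(msg, "thresholds must lie in [0, 50] dB")
  for (r in c(object@fpRate, object@fnRate, object@flRate))
    if (!is.na(r) && (r < 0 || r > 1)) msg <- c(msg, "rates must lie in [0, 1]")
  if (length(object@pdProb) && !all(object@pdProb %in% PD_LEVELS))
    msg <- c(msg, "invalid pdProb category")
  if (length(object@psdProb) && !all(object@psdProb %in% PD_LEVELS))
    msg <- c(msg, "invalid psdProb category")
  if (length(object@ght) && !all(object@ght %in% GHT_LEVELS))
    msg <- c(msg, "invalid ght category")
  if (length(msg)) msg else TRUE
})

#' VFSeries: the date-ordered exams of one eye and pattern
#'
#' @slot eyeId eye identifier shared by all exams.
#' @slot pattern common test pattern.
#' @slot exams list of [VFExam-class] sorted ascending by date.
#' @export
setClass("VFSeries",
  representation(eyeId = "character", pattern = "character", exams = "list"))

setValidity("VFSeries", function(object) {
  msg <- character()
  if (length(object@exams)) {
    ok <- vapply(object@exams, is, logical(1), class2 = "VFExam")
    if (!all(ok)) return("exams must all be VFExam")
    d <- as.numeric(vapply(object@exams, function(e) e@date, as.Date(NA)))
    if (is.unsorted(d)) msg <- c(msg, "exams must be sorted ascending by date")
    if (!all(vapply(object@exams, function(e) e@pattern, "") == object@pattern))
      msg <- c(msg, "all exams must share the series pattern")
    if (!all(vapply(object@exams, function(e) e@eyeId, "") == object@eyeId))
      msg <- c(msg, "all exams must share the series eye")
  }
  if (length(msg)) msg else TRUE
})

#' PairedSample: one OCT volume with its masked 122-value label vector
#'
#' The training unit pairing an OCT volume with the visual-field label
#' vector at the OCT date. The 122 entries are ordered
#' \[52 non-blind-spot 24-2 points, 24-2 MD, 68 10-2 points, 10-2 MD\].
#' `mask` is 1 where the label is absent (those entries carry an inert
#' sentinel of 0 and are excluded from loss and metrics).
#'
#' @slot patientId,eyeId identifiers.
#' @slot octDate date of the OCT acquisition.
#' @slot volumeRef identifier of the paired volume within its dataset.
#' @slot labels numeric length 122.
#' @slot mask numeric length 122 in \{0, 1\}; 1 = absent.
#' @slot provenance named character of length 2 (`p24`, `p10`), each one of
#'   "regressed", "single_exam", "missing".
#' @export
setClass("PairedSample",
  representation(patientId = "character", eyeId = "character",
                 octDate = "Date", volumeRef = "character",
                 labels = "numeric", mask = "numeric",
                 provenance = "character"))

setValidity("PairedSample", function(object) {
  msg <- character()
  if (length(object@labels) != 122L) msg <- c(msg, "labels must have length 122")
  if (length(object@mask) != 122L) msg <- c(msg, "mask must have length 122")
  if (!all(object@mask %in% c(0, 1))) msg <- c(msg, "mask entries must be 0 or 1")
  if (any(!is.finite(object@labels[object@mask == 0])))
    msg <- c(msg, "labels must be finite wherever mask = 0")
  lay <- labelLayout()
  th <- object@labels[lay$idx24]; m <- object@mask[lay$idx24]
  if (any(th[m == 0] < 0 | th[m == 0] > 33))
    msg <- c(msg, "unmasked 24-2 thresholds outside [0, 33] dB")
  md <- object@labels[c(lay$md24, lay$md10)]
  mm <- object@mask[c(lay$md24, lay$md10)]
  if (any(md[mm == 0] < -33 | md[mm == 0] > 0))
    msg <- c(msg, "unmasked MD outside [-33, 0] dB")
  if (!all(object@provenance %in% c("regressed", "single_exam", "missing")))
    msg <- c(msg, "invalid provenance")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VFGrid", function(object) {
  cat(sprintf("VFGrid pattern %s: %d points (%d blind spot), %d rows\n",
              object@pattern, nrow(object@coords), length(object@blindSpot),
              max(object@row)))
})

setMethod("show", "VFExam", function(object) {
  cat(sprintf("VFExam %s %s [%s] %s: %d thresholds (%d NA), MD %.1f dB\n",
              object@eyeId, object@laterality, object@pattern,
              format(object@date), length(object@thresholds),
              sum(is.na(object@thresholds)), object@md))
})

setMethod("show", "VFSeries", function(object) {
  cat(sprintf("VFSeries %s [%s]: %d exams", object@eyeId, object@pattern,
              length(object@exams)))
  if (length(object@exams))
    cat(sprintf(" (%s .. %s)", format(object@exams[[1]]@date),
                format(object@exams[[length(object@exams)]]@date)))
  cat("\n")
})

setMethod("show", "PairedSample", function(object) {
  cat(sprintf(
    "PairedSample %s / %s @ %s: %d/122 labelled (24-2: %s, 10-2: %s)\n",
    object@patientId, object@eyeId, format(object@octDate),
    sum(object@mask == 0), object@provenance[["p24"]],
    object@provenance[["p10"]]))
})

#' Construct a visual-field exam object
#'
#' @param patientId,eyeId identifiers.
#' @param laterality "OD" or "OS".
#' @param date exam date, coerced with `as.Date`.
#' @param pattern "24-2", "10-2" or "30-2".
#' @param thresholds per-point dB thresholds in the native-frame grid order.
#' @param md mean deviation in dB.
#' @param fpRate,fnRate,flRate reliability rates in \[0, 1\].
#' @param pdProb optional per-point pattern-deviation probability categories.
#' @param psdProb,ght optional summary categories.
#' @return a [VFExam-class].
#' @export
VFExam <- function(patientId, eyeId, laterality, date, pattern, thresholds,
                   md = NA_real_, fpRate = NA_real_, fnRate = NA_real_,
                   flRate = NA_real_, pdProb = character(),
                   psdProb = character(), ght = character()) {
  new("VFExam", patientId = as.character(patientId),
      eyeId = as.character(eyeId), laterality = laterality,
      date = as.Date(date), pattern = pattern,
      thresholds = as.numeric(thresholds), md = as.numeric(md),
      fpRate = as.numeric(fpRate), fnRate = as.numeric(fnRate),
      flRate = as.numeric(flRate), pdProb = as.character(pdProb),
      psdProb = as.character(psdProb), ght = as.character(ght))
}

#' Construct a visual-field series from exams
#'
#' Exams are sorted ascending by date; all must share eye and pattern.
#'
#' @param exams list of [VFExam-class].
#' @return a [VFSeries-class].
#' @export
VFSeries <- function(exams) {
  stopifnot(length(exams) > 0)
  d <- vapply(exams, function(e) as.numeric(e@date), numeric(1))
  exams <- exams[order(d)]
  new("VFSeries", eyeId = exams[[1]]@eyeId, pattern = exams[[1]]@pattern,
      exams = exams)
}

#' Number of exams in a series (the n of the validity period)
#' @param series a [VFSeries-class].
#' @return integer count.
#' @export
nTests <- function(series) length(series@exams)

#' @describeIn VFGrid-class number of test points.
#' @param grid a [VFGrid-class].
#' @export
nPoints <- function(grid) nrow(grid@coords)

#' Grid accessors
#'
#' `gridPattern`, `gridPoints`, `blindSpotIndices` and `rowIndex` read the
#' corresponding slots of a [VFGrid-class].
#'
#' @param grid a [VFGrid-class].
#' @return pattern string, coordinate matrix, integer indices or row vector.
#' @export
gridPattern <- function(grid) grid@pattern

#' @rdname gridPattern
#' @export
gridPoints <- function(grid) grid@coords

#' @rdname gridPattern
#' @export
blindSpotIndices <- function(grid) grid@blindSpot

#' @rdname gridPattern
#' @export
rowIndex <- function(grid) grid@row

#' Paired-sample accessors
#'
#' @param sample a [PairedSample-class].
#' @return the label vector, mask vector or provenance.
#' @export
sampleLabels <- function(sample) sample@labels

#' @rdname sampleLabels
#' @export
sampleMask <- function(sample) sample@mask

#' @rdname sampleLabels
#' @export
sampleProvenance <- function(sample) sample@provenance
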