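# Grid geometry of the Humphrey 24-2 / 30-2 / 10-2 patterns, OD frame:
# x > 0 temporal, y > 0 superior, units degrees.

# Literal 10-2 chart, rows superior to inferior, nasal to temporal.
# 68 points at 2 degree spacing; no closed form is assumed, the table is
# validated by count and mirror symmetry in the class validity method.
P10_2_TABLE <- matrix(c(
  -1,  9,   1,  9,
  -5,  7,  -3,  7,  -1,  7,   1,  7,   3,  7,   5,  7,
  -7,  5,  -5,  5,  -3,  5,  -1,  5,   1,  5,   3,  5,   5,  5,   7,  5,
  -7,  3,  -5,  3,  -3,  3,  -1,  3,   1,  3,   3,  3,   5,  3,   7,  3,
  -9,  1,  -7,  1,  -5,  1,  -3,  1,  -1,  1,   1,  1,   3,  1,   5,  1,
   7,  1,   9,  1,
  -9, -1,  -7, -1,  -5, -1,  -3, -1,  -1, -1,   1, -1,   3, -1,   5, -1,
   7, -1,   9, -1,
  -7, -3,  -5, -3,  -3, -3,  -1, -3,   1, -3,   3, -3,   5, -3,   7, -3,
  -7, -5,  -5, -5,  -3, -5,  -1, -5,   1, -5,   3, -5,   5, -5,   7, -5,
  -5, -7,  -3, -7,  -1, -7,   1, -7,   3, -7,   5, -7,
  -1, -9,   1, -9), ncol = 2, byrow = TRUE)

orderGridCoords <- function(coords) {
  coords[order(-coords[, 2], coords[, 1]), , drop = FALSE]
}

#' Build a visual-field test-point grid
#'
#' Constructs the ordered point set of one Humphrey pattern in the OD frame.
#' The 24-2 and 30-2 sets are generated from their lattice definition (odd
#' multiples of 3 degrees inside the pattern's eccentricity bound, plus the
#' 24-2 nasal extension at (-27, +-3)); the 10-2 set is a transcribed chart.
#'
#' @param pattern "24-2", "10-2" or "30-2".
#' @return a [VFGrid-class]; points ordered rows superior to inferior,
#'   within each row nasal (most negative x) to temporal.
#' @examples
#' g <- buildGrid("24-2")
#' nPoints(g)                      # 54
#' length(blindSpotIndices(g))     # 2
#' @export
buildGrid <- function(pattern) {
  pattern <- match.arg(pattern, VF_PATTERNS)
  if (pattern == "10-2") {
    coords <- P10_2_TABLE
  } else {
    ax <- seq(-27, 27, by = 6)  # odd multiples of 3
    coords <- as.matrix(expand.grid(x = ax, y = ax))
    if (pattern == "30-2") {
      coords <- coords[coords[, 1]^2 + coords[, 2]^2 <= 810, , drop = FALSE]
    } else {
      keep <- abs(coords[, 1]) <= 21 & abs(coords[, 2]) <= 21 &
        coords[, 1]^2 + coords[, 2]^2 <= 530
      coords <- rbind(coords[keep, , drop = FALSE],
                      cbind(c(-27, -27), c(3, -3)))
    }
  }
  coords <- orderGridCoords(coords)
  dimnames(coords) <- list(NULL, c("x", "y"))
  bs <- if (pattern %in% c("24-2", "30-2"))
    which(coords[, 1] == 15 & abs(coords[, 2]) == 3) else integer()
  rows <- match(coords[, 2], sort(unique(coords[, 2]), decreasing = TRUE))
  new("VFGrid", pattern = pattern, coords = coords,
      blindSpot = as.integer(bs), row = as.integer(rows))
}

# Native-frame coordinates for a given laterality: the OS chart is the
# x-mirror of the OD chart, re-sorted with the same deterministic rule.
gridNativeCoords <- function(grid, laterality) {
  if (laterality == "OD") return(grid@coords)
  m <- grid@coords
  m[, 1] <- -m[, 1]
  orderGridCoords(m)
}

matchCoords <- function(a, b) {
  match(paste(a[, 1], a[, 2]), paste(b[, 1], b[, 2]))
}

#' Index permutation between OD-frame and OS-native point order
#'
#' Entry j gives the position, in the opposite laterality's native ordering,
#' of the x-mirror of point j. The map is its own inverse, so the same
#' permutation converts OS-native vectors to OD-frame order and back.
#'
#' @param grid a [VFGrid-class].
#' @return integer permutation of `seq_len(nPoints(grid))`.
#' @export
lateralityPermutation <- function(grid) {
  od <- grid@coords
  os <- gridNativeCoords(grid, "OS")
  mir <- od
  mir[, 1] <- -mir[, 1]
  p <- matchCoords(mir, os)
  stopifnot(!anyNA(p))
  p
}

#' Map an exam into the OD frame
#'
#' OS exams have their thresholds (and per-point probability map, if present)
#' re-indexed by the x-mirror permutation and are re-tagged as OD-frame;
#' OD exams are returned unchanged. MD and all summary indices are
#' unaffected.
#'
#' @param exam a [VFExam-class].
#' @param grid the matching [VFGrid-class].
#' @return a [VFExam-class] in OD-frame point order.
#' @export
normalizeLaterality <- function(exam, grid) {
  stopifnot(is(exam, "VFExam"), is(grid, "VFGrid"),
            exam@pattern == grid@pattern)
  if (exam@laterality == "OD") return(exam)
  p <- lateralityPermutation(grid)
  out <- exam
  out@thresholds <- exam@thresholds[p]
  if (length(exam@pdProb)) out@pdProb <- exam@pdProb[p]
  out@laterality <- "OD"
  out
}

#' Vertical (superior-inferior) flip permutation of a grid
#'
#' Entry j gives the index of the point at (x, -y). Every supported pattern
#' is symmetric under this mirror, so the permutation is a well-defined
#' involution; blind-spot indices map onto blind-spot indices.
#'
#' @param grid a [VFGrid-class].
#' @return integer permutation.
#' @export
verticalFlipPermutation <- function(grid) {
  m <- grid@coords
  m[, 2] <- -m[, 2]
  p <- matchCoords(m, grid@coords)
  if (anyNA(p)) stop("grid is not symmetric under vertical mirroring")
  p
}

#' Trim a 30-2 exam to the 24-2 point set
#'
#' Retains the 30-2 points whose coordinates belong to the 24-2 chart
#' (including the nasal extension) and re-tags the exam as 24-2. The
#' device-reported MD is kept as recorded unless `recomputeMd = TRUE`, in
#' which case it is replaced by [simplifiedMD()] against `baseline`.
#'
#' @param exam a 30-2 [VFExam-class] (either laterality).
#' @param recomputeMd recompute MD from the retained points (default FALSE).
#' @param baseline baseline sensitivity used when `recomputeMd = TRUE`.
#' @return a 24-2 [VFExam-class].
#' @export
trim30to24 <- function(exam, recomputeMd = FALSE, baseline = 33) {
  stopifnot(is(exam, "VFExam"))
  if (exam@pattern != "30-2") stop("trim30to24 requires a 30-2 exam")
  g30 <- buildGrid("30-2")
  g24 <- buildGrid("24-2")
  src <- gridNativeCoords(g30, exam@laterality)
  dst <- gridNativeCoords(g24, exam@laterality)
  idx <- matchCoords(dst, src)
  stopifnot(!anyNA(idx))
  out <- exam
  out@pattern <- "24-2"
  out@thresholds <- exam@thresholds[idx]
  if (length(exam@pdProb)) out@pdProb <- exam@pdProb[idx]
  if (recomputeMd) out@md <- simplifiedMD(out, baseline)
  out
}

#' Unweighted surrogate mean deviation
#'
#' Mean of (threshold - baseline) over the non-blind-spot points. A stand-in
#' for the device MD in the synthetic world, where no normative database
#' exists; it is unweighted, unlike the device index.
#'
#' @param exam a [VFExam-class] with complete non-blind-spot thresholds.
#' @param baseline scalar or per-point baseline sensitivity in dB (full grid
#'   length or one value).
#' @return MD surrogate in dB.
#' @export
simplifiedMD <- function(exam, baseline = 33) {
  grid <- buildGrid(exam@pattern)
  keep <- setdiff(seq_len(nPoints(grid)), grid@blindSpot)
  th <- exam@thresholds
  if (length(baseline) == 1) baseline <- rep(baseline, nPoints(grid))
  if (anyNA(th[keep])) stop("simplifiedMD requires complete thresholds")
  mean(th[keep] - baseline[keep])
}

#' Layout of the 122-value label vector
#'
#' The fixed output ordering: positions 1..52 are the non-blind-spot 24-2
#' points (grid order), 53 the 24-2 MD, 54..121 the 68 10-2 points and
#' 122 the 10-2 MD.
#'
#' @return list with `idx24`, `md24`, `idx10`, `md10` (positions in the
#'   vector) and `points24` (the 24-2 grid indices kept).
#' @export
labelLayout <- function() {
  g24 <- buildGrid("24-2")
  points24 <- setdiff(seq_len(54L), g24@blindSpot)
  list(idx24 = 1:52, md24 = 53L, idx10 = 54:121, md10 = 122L,
       points24 = points24)
}

#' Vertical-flip permutation of the 122-value label vector
#'
#' Applies [verticalFlipPermutation()] blockwise: the 52 24-2 entries and 68
#' 10-2 entries are permuted by their grids' vertical mirrors; both MD
#' positions are fixed points. Used to keep labels consistent with a
#' vertically flipped volume during augmentation and test-time averaging.
#'
#' @return integer permutation of length 122 (an involution).
#' @export
labelFlipPermutation <- function() {
  lay <- labelLayout()
  g24 <- buildGrid("24-2")
  g10 <- buildGrid("10-2")
  v24 <- verticalFlipPermutation(g24)
  # induced permutation on the non-blind-spot subset
  sub <- lay$points24
  p24 <- match(v24[sub], sub)
  v10 <- verticalFlipPermutation(g10)
  p <- integer(122)
  p[lay$idx24] <- lay$idx24[p24]
  p[lay$md24] <- lay$md24
  p[lay$idx10] <- lay$idx10[v10]
  p[lay$md10] <- lay$md10
  p
}

#' Export a grid as JSON
#'
#' Writes one record per point: index, x, y, blind_spot flag and row.
#'
#' @param grid a [VFGrid-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportGridJSON <- function(grid, path) {
  df <- data.frame(index = seq_len(nPoints(grid)),
                   x = grid@coords[, 1], y = grid@coords[, 2],
                   blind_spot = seq_len(nPoints(grid)) %in% grid@blindSpot,
                   row = grid@row)
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}
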