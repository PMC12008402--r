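# Plain-text interchange: one-row-per-exam CSV with per-point columns
# named t_x{X}_y{Y} (native-frame signed degrees), plus a JSON mirror.

threshColNames <- function(grid, laterality) {
  co <- gridNativeCoords(grid, laterality)
  sprintf("t_x%d_y%d", co[, 1], co[, 2])
}

examToRow <- function(exam) {
  grid <- buildGrid(exam@pattern)
  meta <- data.frame(patientId = exam@patientId, eyeId = exam@eyeId,
                     laterality = exam@laterality,
                     date = format(exam@date), pattern = exam@pattern,
                     md = exam@md, fpRate = exam@fpRate,
                     fnRate = exam@fnRate, flRate = exam@flRate,
                     psdProb = if (length(exam@psdProb)) exam@psdProb else NA,
                     ght = if (length(exam@ght)) exam@ght else NA)
  th <- as.data.frame(as.list(exam@thresholds))
  names(th) <- threshColNames(grid, exam@laterality)
  if (length(exam@pdProb)) {
    pd <- as.data.frame(as.list(exam@pdProb))
    names(pd) <- sub("^t_", "pd_", names(th))
    cbind(meta, th, pd)
  } else cbind(meta, th)
}

#' Write visual-field exams to CSV
#'
#' One row per exam; per-point thresholds in columns `t_x{X}_y{Y}` using
#' the exam's native-frame coordinates, missing thresholds as empty cells.
#' All exams must share one pattern. A JSON mirror of the same schema is
#' produced by [writeVFExamsJSON()].
#'
#' @param exams list of [VFExam-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeVFExams <- function(exams, path) {
  stopifnot(length(exams) > 0)
  rows <- lapply(exams, examToRow)
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    r[setdiff(cols, names(r))] <- NA
    r[cols]
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeVFExams
#' @export
writeVFExamsJSON <- function(exams, path) {
  rows <- lapply(exams, function(e) as.list(examToRow(e)))
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

blankToMissing <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) character() else as.character(x)
}

rowToExam <- function(r) {
  grid <- buildGrid(r$pattern)
  cols <- threshColNames(grid, r$laterality)
  th <- as.numeric(unlist(r[cols]))
  pdCols <- sub("^t_", "pd_", cols)
  pdRaw <- if (all(pdCols %in% names(r))) unlist(r[pdCols]) else NULL
  pd <- if (!is.null(pdRaw) && any(!is.na(pdRaw) & nzchar(pdRaw)))
    as.character(pdRaw) else character()
  VFExam(r$patientId, r$eyeId, r$laterality, r$date, r$pattern, th,
         md = r$md, fpRate = r$fpRate, fnRate = r$fnRate, flRate = r$flRate,
         pdProb = pd, psdProb = blankToMissing(r$psdProb),
         ght = blankToMissing(r$ght))
}

#' Write / read a volume as a portable text container
#'
#' Plain-text array format (version 1): a JSON metadata sidecar
#' `<path>.json` carrying the format version, dimensions and any metadata,
#' and the voxel values one per line in column-major order.
#'
#' @param volume 3D numeric array.
#' @param path output file (the sidecar gets `.json` appended).
#' @param meta named list stored in the sidecar.
#' @return the path, invisibly (`readVolumeText` returns a list with
#'   `volume` and `meta`).
#' @export
writeVolumeText <- function(volume, path, meta = list()) {
  stopifnot(length(dim(volume)) == 3)
  jsonlite::write_json(c(list(format = "vfoct-volume", version = 1L,
                              dim = dim(volume)), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  writeLines(formatC(as.numeric(volume), format = "g", digits = 17), path)
  invisible(path)
}

#' @rdname writeVolumeText
#' @export
readVolumeText <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "vfoct-volume"))
    stop("not a vfoct volume container")
  vals <- as.numeric(readLines(path))
  list(volume = array(vals, dim = meta$dim),
       meta = meta[setdiff(names(meta), c("format", "version", "dim"))])
}

#' Read visual-field exams from CSV or JSON
#'
#' Inverse of [writeVFExams()] / [writeVFExamsJSON()].
#'
#' @param path file written by the matching writer.
#' @return list of [VFExam-class].
#' @export
readVFExams <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    rows <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- lapply(rows, function(r) {
      r[vapply(r, is.null, logical(1))] <- NA
      r
    })
  } else {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    rows <- split(df, seq_len(nrow(df)))
  }
  lapply(rows, rowToExam)
}
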