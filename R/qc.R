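# Quality-control filters: reliability indices, OCT signal strength,
# automatic upper-eyelid-artifact rule, Anderson-Patella eligibility.

#' Quality-control configuration
#'
#' @param reliabilityCutoff exams with any reliability rate at or above this
#'   fraction are excluded (default 0.33; the bound is inclusive).
#' @param ssiMin minimum OCT signal strength index (default 7; volumes with
#'   SSI below the bound fail).
#' @param eyelidThresholds the three row-difference cutoffs in dB, superior
#'   to inferior (default 6, 6, 8; comparisons are strict).
#' @param eyelidCombine "all" (every difference must exceed its cutoff) or
#'   "any".
#' @param nNasalPoints how many most-nasal points per row enter the row
#'   means (default 3).
#' @return a `QCConfig` list.
#' @export
qcConfig <- function(reliabilityCutoff = 0.33, ssiMin = 7,
                     eyelidThresholds = c(6, 6, 8),
                     eyelidCombine = c("all", "any"), nNasalPoints = 3L) {
  eyelidCombine <- match.arg(eyelidCombine)
  stopifnot(reliabilityCutoff > 0, reliabilityCutoff <= 1,
            length(eyelidThresholds) == 3, all(eyelidThresholds > 0),
            nNasalPoints >= 1)
  structure(list(reliabilityCutoff = reliabilityCutoff, ssiMin = ssiMin,
                 eyelidThresholds = eyelidThresholds,
                 eyelidCombine = eyelidCombine,
                 nNasalPoints = as.integer(nNasalPoints)),
            class = "QCConfig")
}

qcDecision <- function(passed, reason, diagnostics = numeric()) {
  stopifnot((reason == "ok") == passed)
  structure(list(passed = passed, reason = reason,
                 diagnostics = diagnostics), class = "QCDecision")
}

#' @export
print.QCDecision <- function(x, ...) {
  cat(sprintf("QCDecision: %s (%s)\n", if (x$passed) "pass" else "fail",
              x$reason))
  if (length(x$diagnostics))
    cat("  ", paste(names(x$diagnostics), "=",
                    signif(x$diagnostics, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Reliability-index filter
#'
#' Fails when any of the false-positive, false-negative or fixation-loss
#' rates is at or above the cutoff (the device cut of 33% is inclusive:
#' a rate of exactly 0.33 fails).
#'
#' @param exam a [VFExam-class] with all three rates recorded.
#' @param cfg a [qcConfig()].
#' @return a `QCDecision`.
#' @export
reliabilityFilter <- function(exam, cfg = qcConfig()) {
  rates <- c(fp = exam@fpRate, fn = exam@fnRate, fl = exam@flRate)
  if (anyNA(rates)) stop("reliability rates missing; cannot adjudicate")
  if (max(rates) >= cfg$reliabilityCutoff)
    qcDecision(FALSE, "unreliable", rates)
  else qcDecision(TRUE, "ok", rates)
}

#' Automatic upper-eyelid-artifact rule
#'
#' On an OD-frame 24-2 exam, takes the mean of the most-nasal points of each
#' of the four superior rows (y = +21, +15, +9, +3) and forms the three
#' differences d_k = m_{k+1} - m_k, superior to inferior, so that a
#' depressed upper row yields positive differences. The exam is flagged as
#' an eyelid artifact when the differences strictly exceed the cutoffs
#' (default 6, 6, 8 dB; all three by default).
#'
#' The rule is invariant to adding a constant to all thresholds.
#'
#' @param exam an OD-frame 24-2 [VFExam-class].
#' @param grid the 24-2 [VFGrid-class].
#' @param cfg a [qcConfig()].
#' @return a `QCDecision` whose diagnostics carry d1..d3.
#' @export
eyelidArtifactDetect <- function(exam, grid = buildGrid("24-2"),
                                 cfg = qcConfig()) {
  stopifnot(is(exam, "VFExam"))
  if (exam@pattern != "24-2") stop("eyelid rule is defined on 24-2 exams")
  if (exam@laterality != "OD")
    stop("exam must be laterality-normalized (OD frame)")
  ys <- c(21, 15, 9, 3)
  m <- vapply(ys, function(y) {
    r <- which(grid@coords[, 2] == y)
    r <- r[order(grid@coords[r, 1])][seq_len(cfg$nNasalPoints)]
    th <- exam@thresholds[r]
    if (anyNA(th)) stop("missing nasal thresholds in superior rows")
    mean(th)
  }, numeric(1))
  d <- diff(m)  # m2-m1, m3-m2, m4-m3 (positive when upper row depressed)
  names(d) <- c("d1", "d2", "d3")
  hit <- d > cfg$eyelidThresholds
  flagged <- if (cfg$eyelidCombine == "all") all(hit) else any(hit)
  if (flagged) qcDecision(FALSE, "eyelid_artifact", d)
  else qcDecision(TRUE, "ok", d)
}

pdAtLeast <- function(pd, level) {
  # TRUE where the category is at least as strict as `level`
  match(pd, PD_LEVELS) >= match(level, PD_LEVELS)
}

#' Anderson-Patella glaucoma eligibility
#'
#' Eligible when any of: (a) a connected cluster of at least three
#' non-blind-spot points with pattern-deviation probability stricter than
#' 5%, at least one of them stricter than 1%; (b) the PSD probability is
#' stricter than 5%; (c) the glaucoma hemifield test is outside normal
#' limits. Contiguity is 8-neighbourhood on the point lattice
#' (|dx| <= 6 and |dy| <= 6 degrees, not both zero) and clusters may not
#' cross the horizontal meridian.
#'
#' @param exam a [VFExam-class] with `pdProb`, `psdProb` and `ght` present.
#' @param grid the matching [VFGrid-class].
#' @return a `QCDecision` (reason `not_glaucoma_eligible` on failure);
#'   diagnostics carry the largest qualifying cluster size.
#' @export
andersonPatellaEligible <- function(exam, grid = buildGrid(exam@pattern)) {
  if (!length(exam@pdProb) || !length(exam@psdProb) || !length(exam@ght))
    stop("pdProb, psdProb and ght are required")
  if (exam@ght == "outside_normal")
    return(qcDecision(TRUE, "ok", c(rule = 3)))
  if (pdAtLeast(exam@psdProb, "p<5%"))
    return(qcDecision(TRUE, "ok", c(rule = 2)))
  keep <- setdiff(seq_len(nPoints(grid)), grid@blindSpot)
  sig <- keep[pdAtLeast(exam@pdProb[keep], "p<5%")]
  best <- 0
  if (length(sig) >= 3) {
    xy <- grid@coords[sig, , drop = FALSE]
    n <- length(sig)
    adj <- outer(xy[, 1], xy[, 1], function(a, b) abs(a - b) <= 6) &
      outer(xy[, 2], xy[, 2], function(a, b) abs(a - b) <= 6) &
      outer(sign(xy[, 2]), sign(xy[, 2]), "==")
    comp <- connectedComponents(adj)
    for (cid in unique(comp)) {
      members <- sig[comp == cid]
      if (length(members) >= 3 &&
          any(pdAtLeast(exam@pdProb[members], "p<1%"))) {
        best <- max(best, length(members))
      }
    }
  }
  if (best >= 3) qcDecision(TRUE, "ok", c(rule = 1, cluster = best))
  else qcDecision(FALSE, "not_glaucoma_eligible", c(cluster = best))
}

connectedComponents <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i]) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cid
      frontier <- nb
    }
  }
  comp
}

#' OCT signal-strength filter
#'
#' @param ssi recorded signal strength index of the volume.
#' @param cfg a [qcConfig()].
#' @return a `QCDecision`; fails when `ssi < ssiMin` (7 passes).
#' @export
ssiFilter <- function(ssi, cfg = qcConfig()) {
  if (is.na(ssi)) stop("SSI missing")
  if (ssi < cfg$ssiMin) qcDecision(FALSE, "low_ssi", c(ssi = ssi))
  else qcDecision(TRUE, "ok", c(ssi = ssi))
}
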