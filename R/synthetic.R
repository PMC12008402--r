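# Seeded generator of paired synthetic OCT-like volumes and longitudinal
# visual-field series. Emulates the statistical structure the analysis
# assumes: local retinal-layer thinning coupled to field-point sensitivity
# loss (with the vertical retina/field inversion), non-positive pointwise
# progression, test-retest noise, and injectable upper-eyelid artifacts.

#' Synthetic-dataset configuration
#'
#' Defaults describe the study conditions the package is exercised under:
#' one study eye per patient, five exams per eye at 180-day intervals,
#' 33 dB baseline sensitivity, arcuate defects in 60% of eyes with depth
#' ~N(12, 4) dB, progression slopes truncated N(-0.5, 0.5) dB/year,
#' 1 dB test-retest noise, and a structure-function gain of 1 dB of
#' sensitivity loss per unit of layer thinning.
#'
#' @param nPatients number of patients.
#' @param eyesPerPatient eyes sampled per patient (default 1).
#' @param volumeShape OCT volume dimensions (en-face x, en-face y, axial z).
#' @param nLayers number of bright retinal bands rendered.
#' @param baselineSensitivity healthy sensitivity, dB.
#' @param defectPrevalence fraction of eyes with at least one defect.
#' @param defectDepthMean,defectDepthSd defect depth distribution, dB.
#' @param slopeMean,slopeSd progression slope distribution, dB/year
#'   (sampled values are truncated at zero from above).
#' @param testRetestSd per-point test-retest noise, dB.
#' @param examsPerEye exams per series.
#' @param examIntervalDays spacing of exams.
#' @param eyelidArtifactRate fraction of exams receiving an injected
#'   upper-eyelid artifact.
#' @param eyelidArtifactDepth artifact depth scale D, dB: the four superior
#'   rows are depressed by cumulative steps of 2D/3.
#' @param structureFunctionGain dB of sensitivity loss per unit thickness
#'   deficit.
#' @param lowSsiRate fraction of volumes with SSI below 7.
#' @param unreliableRate fraction of exams with a reliability rate >= 0.33.
#' @param osRate fraction of left eyes.
#' @param fieldExtentDeg half-width of the en-face field of view, degrees.
#' @param baseThickness nominal layer thickness, arbitrary um-like units.
#' @param startDate date of the first exam of every series.
#' @param seed integer seed governing all randomness.
#' @return a `GenConfig` list.
#' @export
genConfig <- function(nPatients = 20, eyesPerPatient = 1,
                      volumeShape = c(64L, 64L, 32L), nLayers = 3,
                      baselineSensitivity = 33, defectPrevalence = 0.6,
                      defectDepthMean = 12, defectDepthSd = 4,
                      slopeMean = -0.5, slopeSd = 0.5, testRetestSd = 1,
                      examsPerEye = 5, examIntervalDays = 180,
                      eyelidArtifactRate = 0, eyelidArtifactDepth = 15,
                      structureFunctionGain = 1, lowSsiRate = 0.05,
                      unreliableRate = 0.05, osRate = 0.5,
                      fieldExtentDeg = 30, baseThickness = 100,
                      startDate = as.Date("2020-01-01"), seed = 1L) {
  rates <- c(defectPrevalence, eyelidArtifactRate, lowSsiRate,
             unreliableRate, osRate)
  stopifnot(all(rates >= 0 & rates <= 1), testRetestSd >= 0,
            all(volumeShape > 0), nPatients >= 1, examsPerEye >= 1)
  structure(as.list(environment()), class = "GenConfig")
}

# Map field coordinates (degrees, OD frame) to en-face pixel indices of the
# thickness map. The retinal locus of field point (x, y) is (x, -y): the
# retina is vertically inverted relative to the field.
fieldToEnface <- function(xy, cfg) {
  nx <- cfg$volumeShape[1]; ny <- cfg$volumeShape[2]
  u <- (xy[, 1] / cfg$fieldExtentDeg + 1) / 2 * (nx - 1) + 1
  v <- (-xy[, 2] / cfg$fieldExtentDeg + 1) / 2 * (ny - 1) + 1
  cbind(pmin(pmax(round(u), 1), nx), pmin(pmax(round(v), 1), ny))
}

#' Sample the ground truth of one eye
#'
#' Draws an en-face layer-thickness map (smooth base minus arcuate wedge
#' defects) and derives the per-point true sensitivities of both patterns:
#' `sensitivity = clamp(baseline - gain * deficit, 0, baseline)` with the
#' deficit read at the vertically inverted retinal locus of each field
#' point. Per-point progression slopes are truncated at zero from above.
#'
#' Uses the current RNG state; seed via [makeDataset()] or `set.seed`.
#'
#' @param cfg a [genConfig()].
#' @return a `GroundTruthEye` list with `thickness`, `deficit`, `defects`,
#'   per-pattern `sens` and `slope`, and `laterality`.
#' @export
sampleEye <- function(cfg = genConfig()) {
  nx <- cfg$volumeShape[1]; ny <- cfg$volumeShape[2]
  u <- matrix(seq_len(nx), nx, ny)
  v <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  cu <- (nx + 1) / 2; cv <- (ny + 1) / 2
  r <- sqrt((u - cu)^2 + (v - cv)^2)
  rmax <- sqrt(cu^2 + cv^2)
  # smooth base: gentle foveal dome, does not enter the deficit
  base <- cfg$baseThickness * (0.9 + 0.2 * exp(-(r / (0.35 * rmax))^2))
  deficit <- matrix(0, nx, ny)
  defects <- list()
  if (runif(1) < cfg$defectPrevalence) {
    nDef <- sample(1:2, 1)
    theta <- atan2(v - cv, u - cu)  # +pi/2 = superior retina (large v)
    for (k in seq_len(nDef)) {
      hemis <- sample(c(1, -1), 1)          # superior / inferior retina
      thc <- hemis * pi / 2 + runif(1, -0.5, 0.5)
      thw <- runif(1, 0.3, 0.7)
      rc <- runif(1, 0.25, 0.6) * rmax
      rw <- runif(1, 0.15, 0.3) * rmax
      depth <- max(0, rnorm(1, cfg$defectDepthMean, cfg$defectDepthSd))
      dth <- atan2(sin(theta - thc), cos(theta - thc))
      bump <- depth * exp(-(dth / thw)^2) * exp(-((r - rc) / rw)^2)
      deficit <- deficit + bump
      defects[[k]] <- list(hemisphere = hemis, depth = depth,
                           radius = rc, angle = thc)
    }
  }
  thickness <- pmax(base - deficit, 0.1 * cfg$baseThickness)
  sens <- list(); slope <- list()
  for (pat in c("24-2", "10-2")) {
    g <- buildGrid(pat)
    px <- fieldToEnface(g@coords, cfg)
    def <- deficit[cbind(px[, 1], px[, 2])]
    s <- clampTo(cfg$baselineSensitivity - cfg$structureFunctionGain * def,
                 c(0, cfg$baselineSensitivity))
    sl <- pmin(0, rnorm(nPoints(g), cfg$slopeMean, cfg$slopeSd))
    sens[[pat]] <- s
    slope[[pat]] <- sl
  }
  structure(list(thickness = thickness, base = base, deficit = deficit,
                 defects = defects, sens = sens, slope = slope,
                 laterality = if (runif(1) < cfg$osRate) "OS" else "OD"),
            class = "GroundTruthEye")
}

#' Render a synthetic OCT-like volume for one eye
#'
#' Produces a `volumeShape` array with `nLayers` bright horizontal bands;
#' the innermost band's axial extent follows the eye's thickness map, so
#' local thinning shows as a locally shorter bright column. Speckle-like
#' noise is added throughout. Left-eye volumes are mirrored along the
#' horizontal en-face axis, as acquired by the device.
#'
#' @param eye a `GroundTruthEye`.
#' @param cfg a [genConfig()].
#' @param noiseSd speckle noise standard deviation (intensity units).
#' @return list with `volume` (3D array) and `meta` (laterality, ssi).
#' @export
renderVolume <- function(eye, cfg = genConfig(), noiseSd = 0.05) {
  nx <- cfg$volumeShape[1]; ny <- cfg$volumeShape[2]; nz <- cfg$volumeShape[3]
  vol <- array(0.05, dim = c(nx, ny, nz))
  z0 <- max(2L, round(nz * 0.15))
  # inner band: thickness-following extent, up to ~40% of the axial range
  tv <- round(eye$thickness / cfg$baseThickness * nz * 0.35)
  tv <- pmin(pmax(tv, 1L), round(nz * 0.45))
  zmat <- array(rep(seq_len(nz), each = nx * ny), dim = c(nx, ny, nz))
  tarr <- array(tv, dim = c(nx, ny, nz))
  vol[zmat >= z0 & zmat < z0 + tarr] <- 0.9
  # deeper constant bands (outer retina / RPE analogues)
  zb <- z0 + round(nz * 0.45) + 2L
  for (l in seq_len(max(0L, cfg$nLayers - 1L))) {
    lo <- zb + (l - 1L) * 4L
    if (lo + 1 > nz) break
    vol[, , lo:min(nz, lo + 1L)] <- 0.6
  }
  if (noiseSd > 0)
    vol <- vol + array(rnorm(length(vol), 0, noiseSd), dim = dim(vol))
  if (eye$laterality == "OS") vol <- vol[nx:1, , , drop = FALSE]
  ssi <- if (runif(1) < cfg$lowSsiRate) runif(1, 4, 6.9) else runif(1, 7, 10)
  list(volume = vol, meta = list(laterality = eye$laterality, ssi = ssi))
}

# Cumulative superior-row depressions of an injected eyelid artifact: each
# step is 2/3 of the depth scale, so a 15 dB injection depresses the rows
# y = +21/+15/+9 by 30/20/10 dB, giving expected row differences of 10 dB,
# comfortably past the 6/6/8 rule.
eyelidArtifactProfile <- function(depth) {
  step <- 2 * depth / 3
  c("21" = 3 * step, "15" = 2 * step, "9" = step, "3" = 0)
}

#' Simulate the longitudinal visual-field series of one eye
#'
#' Thresholds follow `clamp(sens + slope * t + N(0, sd), 0, 40)`; the MD is
#' the unweighted surrogate ([simplifiedMD()]) of the measured thresholds.
#' Reliability rates are mostly good, with a configurable unreliable
#' fraction; exams selected for artifact injection have their superior rows
#' depressed by [eyelidArtifactProfile()]. Left-eye exams are emitted in
#' their native (mirrored) point order.
#'
#' @param eye a `GroundTruthEye`.
#' @param pattern "24-2" or "10-2".
#' @param cfg a [genConfig()].
#' @param patientId,eyeId identifiers stored on the exams.
#' @return list with `series` (a [VFSeries-class]) and `artifactExams`
#'   (indices of injected exams).
#' @export
simulateVFSeries <- function(eye, pattern, cfg = genConfig(),
                             patientId = "P1", eyeId = "E1") {
  g <- buildGrid(pattern)
  n <- nPoints(g)
  dates <- cfg$startDate + (seq_len(cfg$examsPerEye) - 1) * cfg$examIntervalDays
  tYears <- as.numeric(dates - dates[1]) / 365.25
  perm <- lateralityPermutation(g)
  artifactExams <- integer()
  exams <- vector("list", cfg$examsPerEye)
  for (i in seq_len(cfg$examsPerEye)) {
    th <- eye$sens[[pattern]] + eye$slope[[pattern]] * tYears[i] +
      rnorm(n, 0, cfg$testRetestSd)
    if (pattern == "24-2" && cfg$eyelidArtifactRate > 0 &&
        runif(1) < cfg$eyelidArtifactRate) {
      prof <- eyelidArtifactProfile(cfg$eyelidArtifactDepth)
      for (y in c(21, 15, 9)) {
        rowIdx <- which(g@coords[, 2] == y)
        th[rowIdx] <- th[rowIdx] - prof[[as.character(y)]]
      }
      artifactExams <- c(artifactExams, i)
    }
    th <- clampTo(th, c(0, 40))
    md <- mean(th[setdiff(seq_len(n), g@blindSpot)] - cfg$baselineSensitivity)
    devTrue <- eye$sens[[pattern]] + eye$slope[[pattern]] * tYears[i] -
      cfg$baselineSensitivity
    pd <- cut(devTrue, breaks = c(-Inf, -10, -7, -5, -3, Inf),
              labels = rev(PD_LEVELS))
    sdDev <- sd(devTrue)
    psd <- if (sdDev >= 3) "p<1%" else if (sdDev >= 2) "p<5%" else "ns"
    sup <- mean(devTrue[g@coords[, 2] > 0])
    inf <- mean(devTrue[g@coords[, 2] < 0])
    ght <- if (abs(sup - inf) > 3) "outside_normal"
    else if (abs(sup - inf) > 1.5) "borderline" else "within_normal"
    unrel <- runif(1) < cfg$unreliableRate
    rates <- runif(3, 0, 0.2)
    if (unrel) rates[sample(3, 1)] <- runif(1, 0.33, 0.5)
    thOut <- th; pdOut <- as.character(pd)
    if (eye$laterality == "OS") {
      thOut <- th[perm]
      pdOut <- pdOut[perm]
    }
    exams[[i]] <- VFExam(patientId, eyeId, eye$laterality, dates[i], pattern,
                         thOut, md = md, fpRate = rates[1], fnRate = rates[2],
                         flRate = rates[3], pdProb = pdOut, psdProb = psd,
                         ght = ght)
  }
  list(series = VFSeries(exams), artifactExams = artifactExams)
}

#' Generate a complete synthetic paired dataset
#'
#' Reproducible from `cfg$seed`: samples every eye's ground truth, renders
#' one OCT volume per eye at the date of its final exam, and simulates the
#' 24-2 and 10-2 longitudinal series. Ground-truth tables are retained for
#' recovery tests.
#'
#' @param cfg a [genConfig()].
#' @return list with `config`, `meta` (one row per volume: patientId, eyeId,
#'   laterality, ssi, octDate, volumeId), `volumes` (named list of arrays),
#'   `series` (per eye, `s24`/`s10` plus artifact indices) and `truth`
#'   (per eye: the `GroundTruthEye` plus the true 122-value label vector at
#'   the OCT date).
#' @export
makeDataset <- function(cfg = genConfig()) {
  set.seed(cfg$seed)
  lay <- labelLayout()
  meta <- list(); volumes <- list(); series <- list(); truth <- list()
  octDate <- cfg$startDate + (cfg$examsPerEye - 1) * cfg$examIntervalDays
  tOct <- as.numeric(octDate - cfg$startDate) / 365.25
  k <- 0
  for (p in seq_len(cfg$nPatients)) {
    for (e in seq_len(cfg$eyesPerPatient)) {
      k <- k + 1
      patientId <- sprintf("P%03d", p)
      eyeId <- sprintf("%s_E%d", patientId, e)
      volumeId <- sprintf("V%04d", k)
      eye <- sampleEye(cfg)
      rv <- renderVolume(eye, cfg)
      s24 <- simulateVFSeries(eye, "24-2", cfg, patientId, eyeId)
      s10 <- simulateVFSeries(eye, "10-2", cfg, patientId, eyeId)
      sens24 <- clampTo(eye$sens[["24-2"]] + eye$slope[["24-2"]] * tOct,
                        c(0, cfg$baselineSensitivity))
      sens10 <- clampTo(eye$sens[["10-2"]] + eye$slope[["10-2"]] * tOct,
                        c(0, cfg$baselineSensitivity))
      lbl <- numeric(122)
      lbl[lay$idx24] <- sens24[lay$points24]
      lbl[lay$md24] <- mean(sens24[lay$points24] - cfg$baselineSensitivity)
      lbl[lay$idx10] <- sens10
      lbl[lay$md10] <- mean(sens10 - cfg$baselineSensitivity)
      meta[[k]] <- data.frame(patientId = patientId, eyeId = eyeId,
                              laterality = eye$laterality,
                              ssi = rv$meta$ssi, octDate = octDate,
                              volumeId = volumeId)
      volumes[[volumeId]] <- rv$volume
      series[[eyeId]] <- list(s24 = s24$series, s10 = s10$series,
                              artifact24 = s24$artifactExams)
      truth[[eyeId]] <- list(eye = eye, trueLabels = lbl)
    }
  }
  list(config = cfg, meta = do.call(rbind, meta), volumes = volumes,
       series = series, truth = truth)
}
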