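# Orchestration: generate -> QC -> label -> train -> evaluate -> compare.
# Reproduces the curated-versus-comprehensive training contrast
# structurally on synthetic data: a curated cohort restricted to
# glaucoma-eligible eyes (the manually cleaned analogue) against a
# comprehensive cohort of every QC-passing sample (artifact-rule filtered),
# trained under identical folds and evaluated on the curated-eligible test
# subset only.

#' Pipeline configuration
#'
#' @param gen a [genConfig()].
#' @param qc a [qcConfig()].
#' @param label a [labelConfig()].
#' @param train a [trainConfig()].
#' @param eval an [evalConfig()].
#' @param foldsToRun how many of the cross-validation folds to train
#'   (default 1; the folds themselves are always the full rotation).
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(gen = genConfig(), qc = qcConfig(),
                           label = labelConfig(), train = trainConfig(),
                           eval = evalConfig(), foldsToRun = 1L) {
  structure(list(gen = gen, qc = qc, label = label, train = train,
                 eval = eval, foldsToRun = as.integer(foldsToRun)),
            class = "PipelineConfig")
}

filterSeries <- function(series, grid, qc, dropArtifacts = FALSE) {
  keep <- vapply(series@exams, function(e) {
    normalized <- normalizeLaterality(e, grid)
    if (!reliabilityFilter(normalized, qc)$passed) return(FALSE)
    if (dropArtifacts && grid@pattern == "24-2" &&
        !eyelidArtifactDetect(normalized, grid, qc)$passed) return(FALSE)
    TRUE
  }, logical(1))
  if (!any(keep)) return(NULL)
  exams <- lapply(series@exams[keep], normalizeLaterality, grid = grid)
  VFSeries(exams)
}

#' Build QC-filtered, labelled samples from a synthetic dataset
#'
#' Applies the SSI filter to volumes, reliability filtering to all exams
#' and the eyelid-artifact rule to 24-2 exams, normalizes laterality
#' (left-eye volumes are un-mirrored, exams re-indexed into the OD frame),
#' assembles the masked 122-value labels at each OCT date, and records each
#' eye's Anderson-Patella eligibility (the curated-cohort criterion).
#'
#' @param ds a [makeDataset()] result.
#' @param qc a [qcConfig()].
#' @param labelCfg a [labelConfig()].
#' @param trainCfg a [trainConfig()] (for volume preprocessing).
#' @return list with `volumes` (voxels x n matrix), `labels`, `masks`,
#'   `patientId`, `eyeId`, `eligible`, `sampleIds` and `dropped` counts.
#' @export
buildSamples <- function(ds, qc = qcConfig(), labelCfg = labelConfig(),
                         trainCfg = trainConfig()) {
  g24 <- buildGrid("24-2"); g10 <- buildGrid("10-2")
  vols <- list(); labels <- list(); masks <- list()
  pid <- character(); eid <- character(); elig <- logical(); sid <- character()
  dropped <- c(low_ssi = 0L, no_vf = 0L)
  for (i in seq_len(nrow(ds$meta))) {
    row <- ds$meta[i, ]
    if (!ssiFilter(row$ssi, qc)$passed) {
      dropped["low_ssi"] <- dropped["low_ssi"] + 1L
      next
    }
    sr <- ds$series[[row$eyeId]]
    s24 <- filterSeries(sr$s24, g24, qc, dropArtifacts = TRUE)
    s10 <- filterSeries(sr$s10, g10, qc)
    sample <- tryCatch(
      assemblePairedSample(s24, s10, row$octDate, row$volumeId,
                           row$patientId, row$eyeId, labelCfg),
      error = function(e) NULL)
    if (is.null(sample)) {
      dropped["no_vf"] <- dropped["no_vf"] + 1L
      next
    }
    vol <- ds$volumes[[row$volumeId]]
    if (row$laterality == "OS") vol <- vol[dim(vol)[1]:1, , , drop = FALSE]
    vols[[length(vols) + 1L]] <- preprocessVolume(vol, trainCfg)
    labels[[length(labels) + 1L]] <- sample@labels
    masks[[length(masks) + 1L]] <- sample@mask
    pid <- c(pid, row$patientId); eid <- c(eid, row$eyeId)
    sid <- c(sid, row$volumeId)
    elig <- c(elig, !is.null(s24) && length(s24@exams) > 0 &&
                andersonPatellaEligible(
                  s24@exams[[length(s24@exams)]], g24)$passed)
  }
  if (!length(vols)) stop("no usable samples after quality control")
  list(volumes = volumesToMatrix(vols),
       labels = do.call(rbind, labels), masks = do.call(rbind, masks),
       patientId = pid, eyeId = eid, eligible = elig, sampleIds = sid,
       dropped = dropped)
}

evalOnSubset <- function(model, samples, idx, evalCfg) {
  lay <- labelLayout()
  pred <- predictVF(model, samples$volumes[, idx, drop = FALSE], tta = TRUE)
  lbl <- samples$labels[idx, , drop = FALSE]
  msk <- samples$masks[idx, , drop = FALSE]
  blocks <- list(p24 = list(pts = lay$idx24, md = lay$md24),
                 p10 = list(pts = lay$idx10, md = lay$md10))
  out <- lapply(blocks, function(b) {
    tryCatch(
      evalReport(pred[, b$pts, drop = FALSE], lbl[, b$pts, drop = FALSE],
                 msk[, b$pts, drop = FALSE], pred[, b$md], lbl[, b$md],
                 msk[, b$md], evalCfg),
      error = function(e) NULL)
  })
  out$pred <- pred
  out
}

perPairErrors <- function(pred, lbl, msk, pts, md) {
  list(rmse = pairwiseRMSE(pred[, pts, drop = FALSE],
                           lbl[, pts, drop = FALSE],
                           msk[, pts, drop = FALSE])$perPair,
       mae = pairwiseMAE(pred[, pts, drop = FALSE],
                         lbl[, pts, drop = FALSE],
                         msk[, pts, drop = FALSE])$perPair,
       md_ae = abs(pred[msk[, md] == 0, md] - lbl[msk[, md] == 0, md]))
}

#' Run the full synthetic experiment
#'
#' Generates the dataset, builds QC-passed labelled samples, trains the
#' comprehensive cohort (all QC-passing samples, eyelid-artifact-rule
#' filtered) and the curated cohort (glaucoma-eligible eyes only) under
#' identical patient-wise folds, evaluates both on the curated-eligible
#' test subset with test-time averaging, and compares their per-pair errors
#' with Bonferroni-corrected Mann-Whitney tests. Fully seeded.
#'
#' @param cfg a [pipelineConfig()].
#' @return an experiment report list.
#' @export
runExperiment <- function(cfg = pipelineConfig()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ds <- stage("generate", makeDataset(cfg$gen))
  samples <- stage("qc_label", buildSamples(ds, cfg$qc, cfg$label, cfg$train))
  folds <- stage("folds", patientWiseFolds(samples$patientId, cfg$train))
  lay <- labelLayout()
  foldReports <- list()
  for (f in seq_len(min(cfg$foldsToRun, length(folds)))) {
    fold <- folds[[f]]
    testIdx <- which(samples$patientId %in% fold$test & samples$eligible)
    modComp <- stage("train_comprehensive",
                     trainFold(samples, fold, cfg$train))
    curFold <- fold
    curFold$train <- intersect(fold$train,
                               samples$patientId[samples$eligible])
    modCur <- stage("train_curated", {
      sub <- samples
      keep <- samples$eligible | !(samples$patientId %in% fold$train)
      sub$volumes <- samples$volumes[, keep, drop = FALSE]
      sub$labels <- samples$labels[keep, , drop = FALSE]
      sub$masks <- samples$masks[keep, , drop = FALSE]
      sub$patientId <- samples$patientId[keep]
      trainFold(sub, curFold, cfg$train)
    })
    if (!length(testIdx)) {
      foldReports[[f]] <- list(fold = f, note = "no eligible test samples")
      next
    }
    evComp <- stage("evaluate", evalOnSubset(modComp, samples, testIdx,
                                             cfg$eval))
    evCur <- stage("evaluate", evalOnSubset(modCur, samples, testIdx,
                                            cfg$eval))
    lbl <- samples$labels[testIdx, , drop = FALSE]
    msk <- samples$masks[testIdx, , drop = FALSE]
    cmp <- stage("compare", {
      res <- list()
      for (blk in list(list(id = "p24", pts = lay$idx24, md = lay$md24),
                       list(id = "p10", pts = lay$idx10, md = lay$md10))) {
        ec <- perPairErrors(evComp$pred, lbl, msk, blk$pts, blk$md)
        eg <- perPairErrors(evCur$pred, lbl, msk, blk$pts, blk$md)
        for (m in c("rmse", "mae", "md_ae")) {
          res[[paste(blk$id, m, sep = "_")]] <-
            tryCatch(compareGroups(ec[[m]], eg[[m]], cfg$eval),
                     error = function(e) NULL)
        }
      }
      res
    })
    foldReports[[f]] <- list(fold = f, comprehensive = evComp[c("p24", "p10")],
                             curated = evCur[c("p24", "p10")],
                             comparison = cmp,
                             selectedEpochs = c(
                               comprehensive = modComp$selectedEpoch,
                               curated = modCur$selectedEpoch))
  }
  list(config = cfg,
       cohorts = list(
         comprehensive_n = length(samples$patientId),
         curated_n = sum(samples$eligible),
         dropped = samples$dropped),
       folds = foldReports)
}
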