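# Training harness: volume preprocessing, patient-wise cross-validation,
# per-output z-score target normalization, masked loss, the linear
# warmup/decay learning-rate schedule, vertical-flip augmentation,
# test-time averaging, and the Adam loop over the compiled 3D regressor.

#' @useDynLib vfoct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Training configuration
#'
#' Defaults follow the training recipe: Adam with mini-batches of 4, the
#' learning rate raised linearly from 6e-4 to 1e-3 over three epochs then
#' lowered back to 6e-4 over five, a 30% dropout head mapped linearly to
#' the 122 outputs with no hidden layer, and patient-wise 10-fold
#' cross-validation at an 8:1:1 ratio. The `small3dcnn` architecture
#' (stacked conv/instance-norm/ReLU blocks, well under 200k parameters at
#' the default channel widths) is the tested configuration; an
#' `efficientnet3d_b0`-scale channel plan can be requested but is intended
#' for GPU-scale runs and is not exercised here.
#'
#' @param inputShape volume shape fed to the network (default 64x64x32).
#' @param intensityRange min-max normalization range (fixed -1..1).
#' @param batchSize mini-batch size (default 4).
#' @param lrStart,lrPeak learning-rate endpoints (defaults 6e-4, 1e-3).
#' @param warmupEpochs,decayEpochs schedule segment lengths (3 and 5; the
#'   scheduled total is their sum).
#' @param dropoutHead dropout fraction in the head (default 0.30).
#' @param nFolds folds for patient-wise cross-validation (default 10).
#' @param arch "small3dcnn" or "efficientnet3d_b0".
#' @param channels conv channel widths per block (small3dcnn default).
#' @param flipProb probability of the vertical-flip augmentation per draw.
#' @param seed seed governing fold shuffling, weight init, augmentation and
#'   dropout.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(inputShape = c(64L, 64L, 32L),
                        intensityRange = c(-1, 1), batchSize = 4,
                        lrStart = 6e-4, lrPeak = 1e-3, warmupEpochs = 3,
                        decayEpochs = 5, dropoutHead = 0.30, nFolds = 10,
                        arch = c("small3dcnn", "efficientnet3d_b0"),
                        channels = NULL, flipProb = 0.5, seed = 1L) {
  arch <- match.arg(arch)
  if (is.null(channels))
    channels <- switch(arch, small3dcnn = c(8L, 16L, 32L, 64L),
                       efficientnet3d_b0 = c(32L, 16L, 24L, 40L, 80L, 112L,
                                             192L, 320L, 1280L))
  stopifnot(length(inputShape) == 3, all(inputShape > 0),
            warmupEpochs >= 1, decayEpochs >= 1,
            dropoutHead >= 0, dropoutHead < 1, nFolds >= 2)
  structure(list(inputShape = as.integer(inputShape),
                 intensityRange = intensityRange, batchSize = batchSize,
                 lrStart = lrStart, lrPeak = lrPeak,
                 warmupEpochs = warmupEpochs, decayEpochs = decayEpochs,
                 epochs = warmupEpochs + decayEpochs,
                 dropoutHead = dropoutHead, nFolds = as.integer(nFolds),
                 arch = arch, channels = as.integer(channels),
                 flipProb = flipProb, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Standardize a volume for the network
#'
#' Trilinear resampling to the configured input shape followed by per-volume
#' min-max normalization onto \[-1, 1\]. A constant volume maps to all
#' zeros.
#'
#' @param volume 3D numeric array.
#' @param cfg a [trainConfig()].
#' @return 3D array of dimension `cfg$inputShape` with values in \[-1, 1\].
#' @export
preprocessVolume <- function(volume, cfg = trainConfig()) {
  if (length(dim(volume)) != 3) stop("volume must be a 3D array")
  d <- dim(volume)
  if (!all(d == cfg$inputShape)) {
    volume <- array(trilinearResampleCpp(as.numeric(volume), as.integer(d),
                                         cfg$inputShape),
                    dim = cfg$inputShape)
  }
  rng <- range(volume)
  if (rng[1] == rng[2]) return(array(0, dim = cfg$inputShape))
  lo <- cfg$intensityRange[1]; hi <- cfg$intensityRange[2]
  array(lo + (volume - rng[1]) / (rng[2] - rng[1]) * (hi - lo),
        dim = cfg$inputShape)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv())) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Patient-wise cross-validation folds
#'
#' Shuffles the unique patient ids by the seed into `nFolds` parts of
#' near-equal size; fold i uses part i as the test set, part i+1 (mod
#' nFolds) as validation and the remaining parts as training, giving the
#' 8:1:1 ratio at 10 folds. Every patient appears in exactly one test part,
#' so samples of one patient never straddle sets within a fold.
#'
#' @param patientIds character vector (one entry per sample is fine; only
#'   unique ids are split).
#' @param cfg a [trainConfig()].
#' @return list of folds, each with `train`, `val`, `test` patient-id sets.
#' @export
patientWiseFolds <- function(patientIds, cfg = trainConfig()) {
  ids <- unique(as.character(patientIds))
  k <- cfg$nFolds
  if (length(ids) < k) stop("fewer patients than folds")
  shuffled <- withSeed(cfg$seed, sample(ids))
  part <- sort(rep(seq_len(k), length.out = length(shuffled)))
  parts <- split(shuffled, part)
  lapply(seq_len(k), function(i) {
    vi <- if (i == k) 1L else i + 1L
    list(test = parts[[i]], val = parts[[vi]],
         train = unlist(parts[-c(i, vi)], use.names = FALSE))
  })
}

#' Per-output z-score normalization statistics
#'
#' Mean and standard deviation of every output position over the unmasked
#' training entries only. A position with no unmasked training entry is an
#' error; a constant position takes the sd floor.
#'
#' @param labels numeric matrix (samples x 122).
#' @param masks matching mask matrix (1 = absent).
#' @param sdFloor lower bound on the standard deviation.
#' @return a `NormStats` object with `mu` and `sd`.
#' @export
targetNormalizer <- function(labels, masks, sdFloor = 1e-6) {
  stopifnot(all(dim(labels) == dim(masks)))
  p <- ncol(labels)
  mu <- numeric(p); sdv <- numeric(p)
  for (j in seq_len(p)) {
    v <- labels[masks[, j] == 0, j]
    if (!length(v))
      stop(sprintf("output position %d has no unmasked training entries", j))
    mu[j] <- mean(v)
    sdv[j] <- max(if (length(v) > 1) sd(v) else 0, sdFloor)
  }
  structure(list(mu = mu, sd = sdv, sdFloor = sdFloor), class = "NormStats")
}

#' Apply / invert target normalization
#'
#' `applyNorm` z-scores each column and zeroes masked positions;
#' `invertNorm` restores the dB scale.
#'
#' @param stats a [targetNormalizer()] result.
#' @param labels matrix (samples x 122).
#' @param masks optional mask matrix; masked entries are set to 0 after
#'   scaling.
#' @return matrix of the same shape.
#' @export
applyNorm <- function(stats, labels, masks = NULL) {
  z <- sweep(sweep(labels, 2, stats$mu), 2, stats$sd, "/")
  if (!is.null(masks)) z[masks == 1] <- 0
  z
}

#' @rdname applyNorm
#' @export
invertNorm <- function(stats, labels) {
  sweep(sweep(labels, 2, stats$sd, "*"), 2, stats$mu, "+")
}

#' Masked mean squared error
#'
#' Mean of squared residuals over the entries with mask 0; entries with
#' mask 1 contribute nothing (residuals are multiplied by (1 - mask) and the
#' normalization counts unmasked entries only).
#'
#' @param pred,target numeric vectors or matrices of equal shape.
#' @param mask matching \{0, 1\} mask (1 = absent).
#' @return scalar loss; an all-masked input is an error.
#' @export
maskedMSE <- function(pred, target, mask) {
  stopifnot(length(pred) == length(target), length(pred) == length(mask))
  w <- 1 - mask
  n <- sum(w)
  if (n == 0) stop("all target entries are masked")
  sum(((pred - target) * w)^2) / n
}

#' Learning-rate schedule
#'
#' Linear from `lrStart` to `lrPeak` across epochs 1..warmup, then linear
#' back to `lrStart` across epochs warmup..warmup+decay (endpoints
#' inclusive): 6e-4 at epoch 1, 1e-3 at epoch 3, 6e-4 at epoch 8 under the
#' defaults.
#'
#' @param epoch integer epoch in 1..(warmup+decay).
#' @param cfg a [trainConfig()].
#' @return learning rate.
#' @export
lrSchedule <- function(epoch, cfg = trainConfig()) {
  w <- cfg$warmupEpochs; d <- cfg$decayEpochs
  if (epoch < 1 || epoch > w + d) stop("epoch outside the scheduled range")
  if (epoch <= w) {
    if (w == 1) return(cfg$lrPeak)
    cfg$lrStart + (epoch - 1) / (w - 1) * (cfg$lrPeak - cfg$lrStart)
  } else {
    cfg$lrPeak + (epoch - w) / d * (cfg$lrStart - cfg$lrPeak)
  }
}

flipVolumeVertical <- function(volume) {
  # superior-inferior en-face axis is the second array dimension
  volume[, dim(volume)[2]:1, , drop = FALSE]
}

#' Vertical-flip augmentation of one paired sample
#'
#' Flips the volume along the superior-inferior en-face axis and permutes
#' the label and mask vectors by the matching [labelFlipPermutation()] (MD
#' entries are fixed points), keeping spatially indexed targets consistent
#' with the image. Applying it twice restores the sample. The horizontal
#' (laterality) flip is deterministic at ingest and never drawn here.
#'
#' @param volume 3D array in the OD frame.
#' @param labels,mask length-122 vectors (any scale).
#' @return list with the flipped `volume`, `labels`, `mask`.
#' @export
augmentSample <- function(volume, labels, mask) {
  p <- labelFlipPermutation()
  list(volume = flipVolumeVertical(volume), labels = labels[p],
       mask = mask[p])
}

cnnInit <- function(cfg, seed) {
  nOut <- 122L
  ch <- cfg$channels
  withSeed(seed, {
    params <- numeric(0)
    cin <- 1L
    for (co in ch) {
      fanIn <- 27 * cin
      params <- c(params, rnorm(fanIn * co, 0, sqrt(2 / fanIn)),
                  rep(1, co), rep(0, co))  # conv W, BN gamma, BN beta
      cin <- co
    }
    params <- c(params, rnorm(cin * nOut, 0, 0.01), rep(0, nOut))
    params
  })
}

cnnInitStats <- function(cfg) {
  # running batch-norm statistics: per block [mean = 0, var = 1]
  unlist(lapply(cfg$channels, function(c) c(rep(0, c), rep(1, c))))
}

volumesToMatrix <- function(volumes) {
  # list of equal-shape 3D arrays -> (voxels x n) matrix
  vapply(volumes, as.numeric, numeric(length(volumes[[1]])))
}

#' Predict the 122-value label vector for volumes
#'
#' @param model a [trainFold()] result.
#' @param volumes list of preprocessed volumes (or a voxels x n matrix).
#' @param tta average the predictions from the original and vertically
#'   flipped input, un-permuting the flipped output (default TRUE).
#' @param denormalize return dB-scale predictions (default TRUE).
#' @return matrix (n x 122).
#' @export
predictVF <- function(model, volumes, tta = TRUE, denormalize = TRUE) {
  if (is.list(volumes)) {
    mat <- volumesToMatrix(volumes)
    dims <- dim(volumes[[1]])
  } else {
    mat <- volumes
    dims <- model$cfg$inputShape
  }
  pred <- t(cnnPredictCpp(model$params, model$runStats, as.integer(dims),
                          model$cfg$channels, mat, 122L))
  if (tta) {
    p <- labelFlipPermutation()
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    idx <- as.vector(outer(outer(seq_len(nx), nx * (rev(seq_len(ny)) - 1),
                                 "+"), nx * ny * (seq_len(nz) - 1), "+"))
    flipped <- mat[idx, , drop = FALSE]
    pf <- t(cnnPredictCpp(model$params, model$runStats, as.integer(dims),
                          model$cfg$channels, flipped, 122L))
    # P is an involution, so P^-1 f(flip(v)) = f(flip(v))[p]
    pred <- 0.5 * (pred + pf[, p, drop = FALSE])
  }
  if (denormalize) pred <- invertNorm(model$norm, pred)
  pred
}

#' Train the volumetric regressor on one fold
#'
#' Trains the compact 3D convolutional regressor (stacked convolution /
#' instance-normalization blocks, global average pooling, 30% dropout and a
#' single linear map to the 122 outputs) from random initialization with
#' Adam under the masked loss and the warmup/decay learning-rate schedule,
#' with the vertical-flip augmentation drawn per training sample. The epoch
#' with the lowest validation masked loss supplies the returned weights.
#' Fully deterministic given `cfg$seed`.
#'
#' @param samples list with `volumes` (list of preprocessed arrays or a
#'   voxels x n matrix), `labels` (n x 122), `masks` (n x 122) and
#'   `patientId` (length n).
#' @param fold one element of [patientWiseFolds()].
#' @param cfg a [trainConfig()].
#' @return list with `params`, `norm`, `valLosses` (per epoch, normalized
#'   scale), `selectedEpoch`, `cfg`.
#' @export
trainFold <- function(samples, fold, cfg = trainConfig()) {
  pid <- as.character(samples$patientId)
  iTr <- which(pid %in% fold$train)
  iVa <- which(pid %in% fold$val)
  if (!length(iTr) || !length(iVa)) stop("fold has empty train or val set")
  mat <- if (is.list(samples$volumes)) volumesToMatrix(samples$volumes)
  else samples$volumes
  dims <- cfg$inputShape
  norm <- targetNormalizer(samples$labels[iTr, , drop = FALSE],
                           samples$masks[iTr, , drop = FALSE])
  Y <- applyNorm(norm, samples$labels, samples$masks)
  M <- samples$masks
  pFlip <- labelFlipPermutation()
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  flipIdx <- as.vector(outer(outer(seq_len(nx), nx * (rev(seq_len(ny)) - 1),
                                   "+"), nx * ny * (seq_len(nz) - 1), "+"))
  ch <- cfg$channels
  nPar <- cnnParamCount(ch, 122L)
  params <- cnnInit(cfg, cfg$seed)
  stopifnot(length(params) == nPar)
  runStats <- cnnInitStats(cfg)
  mAdam <- numeric(nPar); vAdam <- numeric(nPar)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8; tAdam <- 0
  keep <- 1 - cfg$dropoutHead
  cLast <- ch[length(ch)]
  valLosses <- numeric(cfg$epochs)
  best <- list(loss = Inf, params = params, runStats = runStats, epoch = 1L)
  rngSeed <- cfg$seed + 1L
  withSeed(rngSeed, {
    for (epoch in seq_len(cfg$epochs)) {
      lr <- lrSchedule(epoch, cfg)
      ord <- sample(iTr)
      for (b in seq(1, length(ord), by = cfg$batchSize)) {
        bi <- ord[b:min(b + cfg$batchSize - 1, length(ord))]
        nb <- length(bi)
        vols <- mat[, bi, drop = FALSE]
        tgt <- t(Y[bi, , drop = FALSE])
        msk <- t(M[bi, , drop = FALSE])
        doFlip <- runif(nb) < cfg$flipProb
        for (j in which(doFlip)) {
          vols[, j] <- vols[flipIdx, j]
          tgt[, j] <- tgt[pFlip, j]
          msk[, j] <- msk[pFlip, j]
        }
        drop <- matrix(rbinom(cLast * nb, 1, keep) / keep, cLast, nb)
        if (all(msk == 1)) next  # no supervised entry in this batch
        res <- cnnLossGradCpp(params, runStats, dims, ch, vols, tgt, msk,
                              drop, 122L)
        if (!is.finite(res$loss)) stop("training loss diverged (non-finite)")
        runStats <- res$runStats
        tAdam <- tAdam + 1
        g <- res$grad
        mAdam <- b1 * mAdam + (1 - b1) * g
        vAdam <- b2 * vAdam + (1 - b2) * g^2
        mhat <- mAdam / (1 - b1^tAdam)
        vhat <- vAdam / (1 - b2^tAdam)
        params <- params - lr * mhat / (sqrt(vhat) + epsA)
      }
      predVa <- cnnPredictCpp(params, runStats, dims, ch,
                              mat[, iVa, drop = FALSE], 122L)
      valLosses[epoch] <- maskedMSE(t(predVa), Y[iVa, , drop = FALSE],
                                    M[iVa, , drop = FALSE])
      if (valLosses[epoch] < best$loss) {
        best <- list(loss = valLosses[epoch], params = params,
                     runStats = runStats, epoch = epoch)
      }
    }
  })
  list(params = best$params, runStats = best$runStats, norm = norm,
       valLosses = valLosses, selectedEpoch = best$epoch, cfg = cfg)
}
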