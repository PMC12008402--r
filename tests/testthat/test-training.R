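tinyTrainCfg <- function(...) {
  trainConfig(inputShape = c(16L, 16L, 8L), channels = c(4L, 8L),
              seed = 21, ...)
}

randomSamples <- function(n = 12, cfg = tinyTrainCfg(), maskRate = 0.2,
                          seed = 31) {
  set.seed(seed)
  vols <- matrix(rnorm(prod(cfg$inputShape) * n), ncol = n)
  labels <- matrix(runif(n * 122, 0, 33), n, 122)
  masks <- matrix(rbinom(n * 122, 1, maskRate), n, 122)
  masks[1, ] <- 0
  list(volumes = vols, labels = labels, masks = masks,
       patientId = sprintf("P%02d", seq_len(n)))
}

test_that("learning-rate schedule hits the published endpoints", {
  cfg <- trainConfig()
  expect_equal(lrSchedule(1, cfg), 6e-4)
  expect_equal(lrSchedule(2, cfg), 8e-4)
  expect_equal(lrSchedule(3, cfg), 1e-3)
  expect_equal(lrSchedule(8, cfg), 6e-4)
  # linear decay midpoints
  expect_equal(lrSchedule(5.5, cfg), 8e-4)
  expect_error(lrSchedule(0, cfg), "range")
  expect_error(lrSchedule(9, cfg), "range")
})

test_that("patient-wise folds are disjoint, covering and patient-tight", {
  cfg <- trainConfig(seed = 3)
  ids <- sprintf("P%02d", 1:20)
  folds <- patientWiseFolds(ids, cfg)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f$train, 16)
    expect_length(f$val, 2)
    expect_length(f$test, 2)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_setequal(c(f$train, f$val, f$test), ids)
  }
  expect_setequal(unlist(lapply(folds, `[[`, "test")), ids)
  expect_equal(length(unlist(lapply(folds, `[[`, "test"))), 20)
  # samples of one patient follow the patient, never split
  sampleIds <- rep(ids, times = 3)
  f1 <- folds[[1]]
  inSet <- ifelse(sampleIds %in% f1$train, "tr",
                  ifelse(sampleIds %in% f1$val, "va", "te"))
  expect_true(all(tapply(inSet, sampleIds,
                         function(x) length(unique(x))) == 1))
  expect_error(patientWiseFolds(ids[1:9], cfg), "fewer")
  # uneven counts still cover every patient exactly once
  folds23 <- patientWiseFolds(sprintf("Q%02d", 1:23), cfg)
  expect_setequal(unlist(lapply(folds23, `[[`, "test")),
                  sprintf("Q%02d", 1:23))
})

test_that("target normalizer matches hand arithmetic and round-trips", {
  lbl <- matrix(c(10, 20, 30,
                  5, 5, 5,
                  1, 2, 100), nrow = 3)  # 3 samples x 3 outputs
  msk <- matrix(0, 3, 3)
  msk[3, 3] <- 1  # the 100 is absent
  ns <- targetNormalizer(lbl, msk)
  expect_equal(ns$mu, c(mean(c(10, 20, 30)), 5, 1.5))
  expect_equal(ns$sd[1], sd(c(10, 20, 30)))
  expect_equal(ns$sd[2], ns$sdFloor)  # constant column floors
  z <- applyNorm(ns, lbl, msk)
  expect_equal(z[, 2], rep(0, 3))
  expect_equal(z[3, 3], 0)  # masked entry zeroed
  back <- invertNorm(ns, applyNorm(ns, lbl))
  expect_equal(back[msk == 0], lbl[msk == 0])
  mskAll <- msk; mskAll[, 3] <- 1
  expect_error(targetNormalizer(lbl, mskAll), "position 3")
})

test_that("masked MSE equals a brute-force oracle on random instances", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(1:6, 1); p <- sample(2:20, 1)
    pred <- matrix(rnorm(n * p), n, p)
    tgt <- matrix(rnorm(n * p), n, p)
    msk <- matrix(rbinom(n * p, 1, 0.4), n, p)
    if (all(msk == 1)) msk[1, 1] <- 0
    brute <- {
      acc <- 0; cnt <- 0
      for (a in seq_len(n)) for (b in seq_len(p)) if (msk[a, b] == 0) {
        acc <- acc + (pred[a, b] - tgt[a, b])^2; cnt <- cnt + 1
      }
      acc / cnt
    }
    expect_equal(maskedMSE(pred, tgt, msk), brute, tolerance = 1e-10)
  }
  expect_error(maskedMSE(1, 2, 1), "masked")
})

test_that("volume preprocessing maps endpoints and keeps monotone ramps", {
  cfg <- tinyTrainCfg()
  v <- array(runif(prod(cfg$inputShape), 0, 255), dim = cfg$inputShape)
  out <- preprocessVolume(v, cfg)
  expect_equal(min(out), -1)
  expect_equal(max(out), 1)
  expect_equal(dim(out), cfg$inputShape)
  expect_equal(preprocessVolume(array(7, c(4, 4, 4)), cfg),
               array(0, dim = cfg$inputShape))
  # axial ramp stays monotone through trilinear downsampling
  big <- array(rep(seq_len(32), each = 24 * 24), dim = c(24, 24, 32))
  small <- preprocessVolume(big, cfg)
  expect_true(all(diff(small[4, 4, ]) > 0))
  expect_error(preprocessVolume(matrix(1, 2, 2), cfg), "3D")
})

test_that("vertical-flip augmentation is a consistent involution", {
  cfg <- tinyTrainCfg()
  vol <- array(rnorm(prod(cfg$inputShape)), dim = cfg$inputShape)
  lbl <- rnorm(122); msk <- rbinom(122, 1, 0.2)
  a <- augmentSample(vol, lbl, msk)
  b <- augmentSample(a$volume, a$labels, a$mask)
  expect_equal(b$volume, vol)
  expect_equal(b$labels, lbl)
  expect_equal(b$mask, msk)
  # a superior-field label moves to the inferior slot while the volume
  # flips its en-face rows: track one labelled point through both
  lay <- labelLayout()
  co <- gridPoints(g24)[lay$points24, ]
  iSup <- which(co[, 1] == 3 & co[, 2] == 9)
  iInf <- which(co[, 1] == 3 & co[, 2] == -9)
  lbl2 <- numeric(122); lbl2[lay$idx24[iSup]] <- 5
  a2 <- augmentSample(vol, lbl2, msk)
  expect_equal(which(a2$labels != 0), lay$idx24[iInf])
  expect_equal(a2$volume[, 1, ], vol[, dim(vol)[2], ])
})

test_that("masked entries receive exactly zero gradient", {
  set.seed(5)
  dims <- c(8L, 8L, 6L); ch <- c(3L, 4L); nOut <- 9L
  npar <- vfoct:::cnnParamCount(ch, nOut)
  params <- rnorm(npar, 0, 0.2)
  rs <- unlist(lapply(ch, function(c) c(rep(0, c), rep(1, c))))
  vols <- matrix(rnorm(prod(dims) * 2), ncol = 2)
  tgt <- matrix(rnorm(nOut * 2), nOut, 2)
  msk <- matrix(rbinom(nOut * 2, 1, 0.5), nOut, 2)
  msk[1, ] <- 0
  drp <- matrix(1, ch[2], 2)
  base <- vfoct:::cnnLossGradCpp(params, rs, dims, ch, vols, tgt, msk, drp,
                                 nOut)
  tgt2 <- tgt
  tgt2[msk == 1] <- tgt2[msk == 1] + rnorm(sum(msk)) * 50
  pert <- vfoct:::cnnLossGradCpp(params, rs, dims, ch, vols, tgt2, msk, drp,
                                 nOut)
  expect_identical(base$loss, pert$loss)
  expect_identical(base$grad, pert$grad)
  mskAll <- msk; mskAll[] <- 1
  expect_error(vfoct:::cnnLossGradCpp(params, rs, dims, ch, vols, tgt,
                                      mskAll, drp, nOut), "unmasked")
})

test_that("compiled loss gradient matches numerical differentiation", {
  set.seed(6)
  dims <- c(6L, 6L, 4L); ch <- c(2L, 3L); nOut <- 5L
  npar <- vfoct:::cnnParamCount(ch, nOut)
  params <- rnorm(npar, 0, 0.3)
  rs <- unlist(lapply(ch, function(c) c(rep(0, c), rep(1, c))))
  vols <- matrix(rnorm(prod(dims) * 3), ncol = 3)
  tgt <- matrix(rnorm(nOut * 3), nOut, 3)
  msk <- matrix(rbinom(nOut * 3, 1, 0.3), nOut, 3); msk[, 1] <- 0
  drp <- matrix(sample(c(0, 1 / 0.7), ch[2] * 3, replace = TRUE), ch[2], 3)
  g <- vfoct:::cnnLossGradCpp(params, rs, dims, ch, vols, tgt, msk, drp,
                              nOut)$grad
  at <- function(p) vfoct:::cnnLossGradCpp(p, rs, dims, ch, vols, tgt, msk,
                                           drp, nOut)$loss
  idx <- sample(npar, 20)
  for (i in idx) {
    h <- 1e-5
    up <- params; up[i] <- up[i] + h
    dn <- params; dn[i] <- dn[i] - h
    expect_equal(g[i], (at(up) - at(dn)) / (2 * h), tolerance = 1e-4)
  }
})

test_that("test-time averaging equals the hand-built two-view average", {
  cfg <- tinyTrainCfg()
  set.seed(8)
  model <- list(params = rnorm(vfoct:::cnnParamCount(cfg$channels, 122L),
                               0, 0.2),
                runStats = vfoct:::cnnInitStats(cfg),
                norm = list(mu = rep(0, 122), sd = rep(1, 122)),
                cfg = cfg)
  vol <- array(rnorm(prod(cfg$inputShape)), dim = cfg$inputShape)
  plain <- predictVF(model, list(vol), tta = FALSE)
  volFlip <- vol[, dim(vol)[2]:1, , drop = FALSE]
  flipped <- predictVF(model, list(volFlip), tta = FALSE)
  p <- labelFlipPermutation()
  byHand <- 0.5 * (plain + flipped[, p, drop = FALSE])
  expect_equal(predictVF(model, list(vol), tta = TRUE), byHand,
               tolerance = 1e-12)
  # a constant-output model is unchanged by averaging
  zeroModel <- model
  zeroModel$params[] <- 0
  cOut <- predictVF(zeroModel, list(vol), tta = TRUE)
  expect_equal(unname(cOut[1, ]), rep(0, 122))
})

test_that("fold training is seed-reproducible and selects a valid epoch", {
  cfg <- tinyTrainCfg()
  samp <- randomSamples(12, cfg)
  folds <- patientWiseFolds(samp$patientId, cfg)
  m1 <- trainFold(samp, folds[[1]], cfg)
  m2 <- trainFold(samp, folds[[1]], cfg)
  expect_identical(m1$valLosses, m2$valLosses)
  expect_identical(m1$params, m2$params)
  expect_true(m1$selectedEpoch >= 1 && m1$selectedEpoch <= cfg$epochs)
  expect_equal(m1$valLosses[m1$selectedEpoch], min(m1$valLosses))
  expect_length(m1$valLosses, 8)
  # a different seed changes the trajectory
  cfg3 <- tinyTrainCfg(); cfg3$seed <- 99L
  m3 <- trainFold(samp, folds[[1]], cfg3)
  expect_false(identical(m1$valLosses, m3$valLosses))
})
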