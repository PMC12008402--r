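test_that("pointwise regression reproduces the closed-form OLS examples", {
  cfg <- labelConfig()
  # two points (0y, 30), (1y, 28); read at 0.5y -> 29
  s <- seriesFromValues(as.Date("2020-01-01") + c(0, 365.25), c(30, 28))
  lab <- pointwiseRegressionLabel(s, 1, as.Date("2020-01-01") + 182.625, cfg)
  expect_equal(lab$value, 29, tolerance = 1e-9)
  expect_equal(lab$source, "regressed")
  # improving series: slope clamped to zero, label = series mean
  s2 <- seriesFromValues(as.Date("2020-01-01") + c(0, 365.25), c(20, 24))
  lab2 <- pointwiseRegressionLabel(s2, 1, as.Date("2021-06-01"), cfg)
  expect_equal(lab2$value, 22)
  # raw extrapolation below zero is floored at 0 dB
  s3 <- seriesFromValues(as.Date("2020-01-01") + c(0, 365.25), c(2, 0))
  lab3 <- pointwiseRegressionLabel(s3, 1, as.Date("2020-01-01") + 3 * 365.25,
                                   cfg)
  expect_equal(lab3$value, 0)
})

test_that("noise-free declining series are recovered exactly at any date", {
  cfg <- labelConfig()
  set.seed(3)
  for (rep in 1:20) {
    a <- runif(1, 10, 33)
    b <- -runif(1, 0, 3)
    d0 <- as.Date("2018-05-05")
    dates <- d0 + sort(sample(0:2000, sample(2:6, 1)))
    t <- as.numeric(dates - d0) / 365.25
    s <- seriesFromValues(dates, a + b * t)
    oct <- d0 + sample(0:2000, 1)
    tOct <- as.numeric(oct - d0) / 365.25
    lab <- pointwiseRegressionLabel(s, 1, oct, cfg)
    expect_equal(lab$value, min(max(a + b * tOct, 0), 33), tolerance = 1e-9)
  }
})

test_that("regression labels are invariant to shifting all dates", {
  cfg <- labelConfig()
  d0 <- as.Date("2019-01-01")
  dates <- d0 + c(0, 200, 500, 900)
  vals <- c(30, 28, 27, 24)
  s1 <- seriesFromValues(dates, vals)
  s2 <- seriesFromValues(dates + 1234, vals)
  l1 <- pointwiseRegressionLabel(s1, 1, d0 + 600, cfg)
  l2 <- pointwiseRegressionLabel(s2, 1, d0 + 600 + 1234, cfg)
  expect_equal(l1$value, l2$value, tolerance = 1e-9)
})

test_that("single-exam pairing honours the six-month window", {
  cfg <- labelConfig()
  s <- seriesFromValues(as.Date("2020-01-01"), 27)
  in5mo <- pointwiseRegressionLabel(s, 1, as.Date("2020-06-01"), cfg)
  expect_equal(in5mo$value, 27)
  expect_equal(in5mo$source, "single_exam")
  out7mo <- pointwiseRegressionLabel(s, 1, as.Date("2020-08-15"), cfg)
  expect_true(is.na(out7mo$value))
  # duplicate dates fall back to the mean
  dup <- seriesFromValues(rep(as.Date("2020-01-01"), 2) + c(0, 0), c(20, 30))
  expect_equal(pointwiseRegressionLabel(dup, 1, as.Date("2020-03-01"),
                                        cfg)$value, 25)
})

test_that("validity period is six months per test", {
  cfg <- labelConfig()
  d0 <- as.Date("2020-01-01")
  mo <- 365.25 / 12
  s2 <- seriesFromValues(d0 + c(-300, 0), c(30, 29))
  expect_true(validityPeriodCheck(s2, d0 + 11 * mo, cfg))   # 11 <= 12
  expect_false(validityPeriodCheck(s2, d0 + 13 * mo, cfg))  # 13 > 12
  s10 <- seriesFromValues(d0 + seq(0, 900, length.out = 10), rep(30, 10))
  expect_true(validityPeriodCheck(s10, d0 + 900 + 59 * mo, cfg))  # 59 <= 60
  expect_false(validityPeriodCheck(s10, d0 + 900 + 61 * mo, cfg))
})

test_that("assembled samples have the 122-slot masked structure", {
  d0 <- as.Date("2020-01-01")
  s24 <- seriesFromValues(d0 + c(0, 180, 360), c(30, 29, 28))
  s10 <- seriesFromValues(d0 + c(0, 180, 360), c(31, 30, 29),
                          pattern = "10-2")
  ps <- assemblePairedSample(s24, s10, d0 + 360, "V1", "P1", "E1")
  expect_s4_class(ps, "PairedSample")
  expect_equal(length(sampleLabels(ps)), 122)
  expect_equal(sum(sampleMask(ps)), 0)
  expect_equal(unname(sampleProvenance(ps)), c("regressed", "regressed"))
  lay <- labelLayout()
  expect_equal(unname(sampleLabels(ps)[lay$idx24]), rep(28, 52),
               tolerance = 1e-9)
  expect_equal(unname(sampleLabels(ps)[lay$md10]), 29 - 33, tolerance = 1e-9)
  # 10-2 never tested: exactly 69 masked
  ps2 <- assemblePairedSample(s24, NULL, d0 + 360, "V1", "P1", "E1")
  expect_equal(sum(sampleMask(ps2)), 69)
  expect_equal(unname(sampleProvenance(ps2)[["p10"]]), "missing")
  # 24-2 fails validity (gap 40 months > 18): 53 masked, 69 unmasked
  s10late <- seriesFromValues(d0 + c(1230, 1410, 1590), c(31, 30, 29),
                              pattern = "10-2")
  ps3 <- assemblePairedSample(s24, s10late, d0 + 360 + 1230, "V1", "P1",
                              "E1")
  expect_equal(sum(sampleMask(ps3)[c(lay$idx24, lay$md24)]), 53)
  expect_equal(sum(sampleMask(ps3) == 0), 69)
  expect_error(assemblePairedSample(NULL, NULL, d0, "V1", "P1", "E1"),
               "usable")
})

test_that("MD labels are regressed as their own series and clamped", {
  d0 <- as.Date("2020-01-01")
  s24 <- seriesFromValues(d0 + c(0, 365.25), c(30, 28),
                          md = c(-30, -36))
  ps <- assemblePairedSample(s24, NULL, d0 + 2 * 365.25, "V1", "P1", "E1")
  lay <- labelLayout()
  # MD line reaches -42 at the OCT date; clamped to -33
  expect_equal(unname(sampleLabels(ps)[lay$md24]), -33)
})

test_that("masked positions are inert for downstream statistics", {
  d0 <- as.Date("2020-01-01")
  s24 <- seriesFromValues(d0 + c(0, 180), c(30, 29))
  ps <- assemblePairedSample(s24, NULL, d0 + 180, "V1", "P1", "E1")
  lbl <- matrix(sampleLabels(ps), 1)
  msk <- matrix(sampleMask(ps), 1)
  pred <- lbl + 1
  base <- maskedMSE(pred, lbl, msk)
  lbl2 <- lbl
  lbl2[msk == 1] <- 1e6  # garbage behind the mask
  expect_equal(maskedMSE(pred, lbl2, msk), base)
  expect_equal(pairwiseMAE(pred, lbl2, msk)$mean,
               pairwiseMAE(pred, lbl, msk)$mean)
})
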