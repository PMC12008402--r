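randomBlock <- function(n, p, maskRate = 0.3) {
  list(pred = matrix(rnorm(n * p, 20, 6), n, p),
       lbl = matrix(rnorm(n * p, 20, 6), n, p),
       msk = matrix(rbinom(n * p, 1, maskRate), n, p))
}

test_that("pairwise RMSE/MAE follow the per-pair-then-average convention", {
  # two pairs with per-pair RMSE 3 and 5 -> mean 4 (not pooled sqrt(17))
  pred <- rbind(rep(3, 4), rep(5, 4))
  lbl <- matrix(0, 2, 4)
  msk <- matrix(0, 2, 4)
  r <- pairwiseRMSE(pred, lbl, msk)
  expect_equal(r$mean, 4)
  expect_equal(r$sd, sd(c(3, 5)))
  m <- pairwiseMAE(rbind(c(2, -2), c(3, 3)), matrix(0, 2, 2),
                   matrix(0, 2, 2))
  expect_equal(m$mean, mean(c(2, 3)))
  expect_equal(pairwiseRMSE(lbl, lbl, msk)$mean, 0)
})

test_that("pairwise metrics match brute-force oracles on random instances", {
  set.seed(23)
  for (i in 1:100) {
    b <- randomBlock(sample(2:8, 1), sample(3:15, 1))
    if (any(rowSums(1 - b$msk) == 0)) b$msk[, 1] <- 0
    bruteR <- mean(sapply(seq_len(nrow(b$pred)), function(j) {
      k <- b$msk[j, ] == 0
      sqrt(mean((b$pred[j, k] - b$lbl[j, k])^2))
    }))
    bruteM <- mean(sapply(seq_len(nrow(b$pred)), function(j) {
      k <- b$msk[j, ] == 0
      mean(abs(b$pred[j, k] - b$lbl[j, k]))
    }))
    expect_equal(pairwiseRMSE(b$pred, b$lbl, b$msk)$mean, bruteR,
                 tolerance = 1e-12)
    expect_equal(pairwiseMAE(b$pred, b$lbl, b$msk)$mean, bruteM,
                 tolerance = 1e-12)
    # per pair, RMSE dominates MAE (power-mean inequality)
    rr <- pairwiseRMSE(b$pred, b$lbl, b$msk)$perPair
    mm <- pairwiseMAE(b$pred, b$lbl, b$msk)$perPair
    expect_true(all(rr >= mm - 1e-12))
  }
})

test_that("all-masked pairs are excluded with a warning", {
  b <- randomBlock(3, 4, 0)
  b$msk[2, ] <- 1
  expect_warning(r <- pairwiseRMSE(b$pred, b$lbl, b$msk), "excluded")
  expect_length(r$perPair, 2)
  b$msk[] <- 1
  expect_error(suppressWarnings(pairwiseRMSE(b$pred, b$lbl, b$msk)))
})

test_that("pooled correlations match direct rank computation", {
  expect_equal(correlations(1:10, 1:10)$pearson_r, 1)
  expect_equal(correlations(1:10, 1:10)$spearman_rho, 1)
  expect_equal(correlations(1:10, -(1:10))$pearson_r, -1)
  set.seed(29)
  for (i in 1:50) {
    x <- rnorm(sample(5:30, 1)); y <- rnorm(length(x)) + 0.5 * x
    got <- correlations(x, y)
    expect_equal(got$pearson_r, cor(x, y), tolerance = 1e-12)
    expect_equal(got$spearman_rho, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(correlations(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlations(rep(1, 5), 1:5), "variance")
})

test_that("Bland-Altman reproduces the closed-form bias and limits", {
  expect_equal(blandAltman(1:5, 1:5)$bias, 0)
  expect_equal(blandAltman(1:5, 1:5)$loa_high, 0)
  est <- c(3, 1, 2.5); act <- c(2, 2, 2.5)
  d <- est - act
  ba <- blandAltman(est, act)
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$proportional_r, cor((est + act) / 2, d))
  expect_true(ba$loa_low <= ba$bias && ba$bias <= ba$loa_high)
  # constructed null: differences independent of magnitude
  set.seed(31)
  act2 <- rep(seq(-30, 0, length.out = 40), each = 2)
  d2 <- rep(c(-1, 1), 40)
  ba2 <- blandAltman(act2 + d2 / 2, act2 - d2 / 2)
  expect_lt(abs(ba2$proportional_r), 0.2)
  expect_error(blandAltman(1:2, 1:2), "3 pairs")
})

test_that("severity strata use the stated closed/open boundaries", {
  n <- 6
  pred <- matrix(rnorm(n * 4, 20), n, 4)
  lbl <- matrix(rnorm(n * 4, 20), n, 4)
  msk <- matrix(0, n, 4)
  md <- c(-5.99, -6, -11.99, -12, -20, 0)
  st <- severityStrata(pred, lbl, msk, md)
  expect_equal(st$mild$n, 2)      # -5.99 and 0
  expect_equal(st$moderate$n, 2)  # -6 and -11.99
  expect_equal(st$severe$n, 2)    # -12 and -20
  st2 <- severityStrata(pred[1:2, ], lbl[1:2, ], msk[1:2, ], c(-1, -2))
  expect_null(st2$severe)
})

test_that("pointwise MAE maps isolate injected errors", {
  n <- 5; p <- 52
  lbl <- matrix(rnorm(n * p, 25, 3), n, p)
  msk <- matrix(0, n, p)
  pred <- lbl
  exact <- pointwiseMAEMap(pred, lbl, msk, g24)
  expect_equal(exact$mae, rep(0, 52))
  expect_equal(nrow(exact), 52)  # blind spot omitted
  pred[, 7] <- lbl[, 7] + c(2, -4, 2, 4, -3)
  one <- pointwiseMAEMap(pred, lbl, msk, g24)
  expect_equal(which(one$mae != 0), 7)
  expect_equal(one$mae[7], 3)
  # a fully masked point is NA
  msk[, 9] <- 1
  expect_true(is.na(pointwiseMAEMap(pred, lbl, msk, g24)$mae[9]))
})

test_that("Mann-Whitney enumeration reproduces exact p-values", {
  # {1,2,3} vs {10,11,12}: U = 0, exact two-sided p = 0.1
  expect_equal(compareGroups(c(1, 2, 3), c(10, 11, 12),
                             evalConfig(bonferroniM = 1))$p_raw, 0.1)
  # identical groups -> corrected p caps at 1
  expect_equal(compareGroups(c(1, 2, 3), c(1, 2, 3))$p_corrected, 1)
  # Bonferroni multiplies and caps
  res <- compareGroups(c(1, 2, 3), c(10, 11, 12),
                       evalConfig(bonferroniM = 6))
  expect_equal(res$p_corrected, min(1, 0.1 * 6))
  # tie-free exact branch agrees with the reference implementation
  set.seed(37)
  for (i in 1:30) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    ours <- compareGroups(a, b, evalConfig(bonferroniM = 1))$p_raw
    ref <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12, info = paste("rep", i))
  }
  expect_error(compareGroups(numeric(), 1:3), "empty")
})

test_that("large-sample comparison uses the tie-corrected approximation", {
  set.seed(41)
  a <- round(rnorm(30, 0, 2)); b <- round(rnorm(25, 1, 2))
  ours <- compareGroups(a, b, evalConfig(bonferroniM = 1))$p_raw
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE)$p.value)
  expect_equal(ours, ref)
})

test_that("quadratic severity regression matches the normal equations", {
  # exact interpolation of y = x^2
  r <- severityErrorRegression(c(-1, 0, 1), c(1, 0, 1))
  expect_equal(r$coef, c(0, 0, 1), tolerance = 1e-10)
  set.seed(43)
  for (i in 1:30) {
    x <- rnorm(10); y <- abs(rnorm(10))
    X <- cbind(1, x, x^2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    got <- severityErrorRegression(x, y)
    expect_equal(got$coef, as.numeric(beta), tolerance = 1e-8)
    expect_equal(got$spearman_rho, cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(severityErrorRegression(c(1, 1, 2), abs(rnorm(3))),
               "distinct")
  expect_error(severityErrorRegression(c(1, 2, 3), c(2, 2, 2)), "constant")
})

test_that("a perfect prediction yields the identity report", {
  set.seed(47)
  n <- 8
  lbl <- matrix(runif(n * 52, 0, 33), n, 52)
  msk <- matrix(rbinom(n * 52, 1, 0.1), n, 52)
  md <- runif(n, -25, 0)
  rep <- evalReport(lbl, lbl, msk, md, md, rep(0, n))
  expect_equal(rep$rmse$mean, 0)
  expect_equal(rep$mae$mean, 0)
  expect_equal(rep$md_mae$mean, 0)
  expect_equal(rep$cor_points$pearson_r, 1)
  expect_equal(rep$bland_altman$bias, 0)
})

test_that("every metric ignores values planted behind the mask", {
  set.seed(53)
  b <- randomBlock(6, 10, 0.3)
  b$msk[, 1] <- 0
  garbage <- b$lbl
  garbage[b$msk == 1] <- 1e9
  expect_equal(pairwiseRMSE(b$pred, garbage, b$msk)$mean,
               pairwiseRMSE(b$pred, b$lbl, b$msk)$mean)
  expect_equal(correlations(b$pred, garbage, b$msk),
               correlations(b$pred, b$lbl, b$msk))
  expect_equal(pointwiseMAEMap(b$pred, garbage, b$msk)$mae,
               pointwiseMAEMap(b$pred, b$lbl, b$msk)$mae)
})
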