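# Agreement and error analysis over paired predictions and labels:
# per-pair RMSE/MAE, pooled correlations, Bland-Altman limits of agreement,
# severity strata, pointwise error maps, Mann-Whitney group comparisons and
# the severity-versus-error quadratic regression. Every statistic ignores
# masked entries entirely.

#' Evaluation configuration
#'
#' @param severityBounds dB cut points for the mild / moderate / severe MD
#'   strata: mild MD > bounds\[1\], moderate bounds\[2\] < MD <= bounds\[1\],
#'   severe MD <= bounds\[2\] (defaults -6, -12).
#' @param loaZ z multiplier of the limits of agreement (default 1.96).
#' @param bonferroniM number of simultaneous comparisons (default 6).
#' @return an `EvalConfig` list.
#' @export
evalConfig <- function(severityBounds = c(-6, -12), loaZ = 1.96,
                       bonferroniM = 6) {
  stopifnot(severityBounds[1] > severityBounds[2], loaZ > 0,
            bonferroniM >= 1)
  structure(list(severityBounds = severityBounds, loaZ = loaZ,
                 bonferroniM = bonferroniM), class = "EvalConfig")
}

perPairStat <- function(preds, labels, masks, fun) {
  stopifnot(all(dim(preds) == dim(labels)), all(dim(preds) == dim(masks)))
  vals <- vapply(seq_len(nrow(preds)), function(i) {
    k <- masks[i, ] == 0
    if (!any(k)) return(NA_real_)
    fun(preds[i, k], labels[i, k])
  }, numeric(1))
  if (anyNA(vals)) {
    warning(sprintf("%d all-masked pair(s) excluded", sum(is.na(vals))))
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) stop("no pair with unmasked entries")
  list(mean = mean(vals), sd = if (length(vals) > 1) sd(vals) else 0,
       perPair = vals)
}

#' Pairwise root-mean-square error
#'
#' The RMSE is computed for each estimated/actual pair over its unmasked
#' entries first, and the per-pair values are then averaged; the spread is
#' the across-pair standard deviation (the "mean +- sd" convention of the
#' summary tables).
#'
#' @param preds,labels,masks matrices (pairs x outputs) of one grid block.
#' @return list with `mean`, `sd` and the `perPair` values.
#' @export
pairwiseRMSE <- function(preds, labels, masks) {
  perPairStat(preds, labels, masks,
              function(p, l) sqrt(mean((p - l)^2)))
}

#' Pairwise mean absolute error
#'
#' Same per-pair-then-average convention as [pairwiseRMSE()]. For the MD
#' MAE, pass the single MD column.
#'
#' @param preds,labels,masks matrices (pairs x outputs).
#' @return list with `mean`, `sd` and the `perPair` values.
#' @export
pairwiseMAE <- function(preds, labels, masks) {
  perPairStat(preds, labels, masks, function(p, l) mean(abs(p - l)))
}

#' Pooled Pearson and Spearman correlations
#'
#' Pools all unmasked (prediction, label) pairs; Spearman is Pearson on
#' average-ranked data.
#'
#' @param preds,labels,masks equal-shape matrices or vectors.
#' @return list with `pearson_r` and `spearman_rho`.
#' @export
correlations <- function(preds, labels, masks = NULL) {
  if (is.null(masks)) masks <- array(0, dim = dim(as.matrix(preds)))
  k <- masks == 0
  x <- as.numeric(preds[k]); y <- as.numeric(labels[k])
  if (length(x) < 3) stop("need at least 3 pooled unmasked values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in pooled values")
  list(pearson_r = cor(x, y),
       spearman_rho = cor(rank(x), rank(y)))
}

#' Bland-Altman agreement analysis
#'
#' Differences are estimated minus actual. Reports the bias (mean
#' difference), the 95% limits of agreement `bias +- loaZ * sd(d)` and the
#' proportional-bias correlation between pair means and differences.
#'
#' @param est,act numeric vectors (e.g. estimated and actual MD).
#' @param cfg an [evalConfig()].
#' @return list with `bias`, `loa_low`, `loa_high`, `proportional_r`.
#' @export
blandAltman <- function(est, act, cfg = evalConfig()) {
  stopifnot(length(est) == length(act))
  if (length(est) < 3) stop("Bland-Altman needs at least 3 pairs")
  d <- est - act
  m <- (est + act) / 2
  bias <- mean(d)
  s <- sd(d)
  pr <- if (sd(m) == 0 || s == 0) 0 else cor(m, d)
  list(bias = bias, loa_low = bias - cfg$loaZ * s,
       loa_high = bias + cfg$loaZ * s, proportional_r = pr)
}

#' Severity-stratified metrics
#'
#' Partitions pairs by actual MD into mild (MD > -6), moderate
#' (-12 < MD <= -6) and severe (MD <= -12) strata and computes the pairwise
#' MAE and pooled correlations per stratum. Empty strata are reported as
#' `NULL`, not errors.
#'
#' @param preds,labels,masks threshold matrices (pairs x points).
#' @param actualMD actual MD per pair.
#' @param cfg an [evalConfig()].
#' @return named list of per-stratum results (with `n` pairs each).
#' @export
severityStrata <- function(preds, labels, masks, actualMD,
                           cfg = evalConfig()) {
  b <- cfg$severityBounds
  ok <- !is.na(actualMD)
  strata <- list(mild = ok & actualMD > b[1],
                 moderate = ok & actualMD <= b[1] & actualMD > b[2],
                 severe = ok & actualMD <= b[2])
  lapply(strata, function(k) {
    if (!any(k)) return(NULL)
    p <- preds[k, , drop = FALSE]; l <- labels[k, , drop = FALSE]
    m <- masks[k, , drop = FALSE]
    res <- list(n = sum(k), mae = pairwiseMAE(p, l, m)["mean"])
    res$cor <- tryCatch(correlations(p, l, m), error = function(e) NULL)
    res
  })
}

#' Pointwise mean-absolute-error map
#'
#' MAE per grid point over the unmasked samples, for error heatmaps.
#' Points with no unmasked sample are `NA`.
#'
#' @param preds,labels,masks matrices (pairs x points) of one grid block,
#'   laterality-normalized (left-eye data already mapped to the OD frame).
#' @param grid the matching [VFGrid-class] (used only for its coordinates;
#'   the columns must already exclude blind-spot points).
#' @return data.frame with x, y and mae per point.
#' @export
pointwiseMAEMap <- function(preds, labels, masks, grid = NULL) {
  err <- abs(preds - labels)
  unm <- masks == 0
  mae <- vapply(seq_len(ncol(err)), function(j) {
    k <- unm[, j]
    if (!any(k)) return(NA_real_)
    mean(err[k, j])
  }, numeric(1))
  if (!is.null(grid)) {
    keep <- setdiff(seq_len(nPoints(grid)), blindSpotIndices(grid))
    stopifnot(length(keep) == length(mae))
    data.frame(x = grid@coords[keep, 1], y = grid@coords[keep, 2],
               mae = mae)
  } else data.frame(point = seq_along(mae), mae = mae)
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments;
# valid with ties (the permutation null of the U statistic).
mannWhitneyExact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  rk <- rank(pooled)
  uOf <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  u <- uOf(seq_len(n1))
  combos <- combn(n, n1)
  us <- apply(combos, 2, uOf)
  pLow <- mean(us <= u)
  pHigh <- mean(us >= u)
  min(1, 2 * min(pLow, pHigh))
}

#' Two-sided Mann-Whitney U comparison with Bonferroni correction
#'
#' Exact enumeration of the permutation null when the smaller group has at
#' most 8 observations; the tie-corrected normal approximation otherwise.
#' The p value is multiplied by the Bonferroni factor and capped at 1.
#'
#' @param errorsA,errorsB the two error samples.
#' @param cfg an [evalConfig()].
#' @return list with `p_raw` and `p_corrected`.
#' @export
compareGroups <- function(errorsA, errorsB, cfg = evalConfig()) {
  if (!length(errorsA) || !length(errorsB)) stop("empty group")
  if (min(length(errorsA), length(errorsB)) <= 8) {
    p <- mannWhitneyExact(errorsA, errorsB)
  } else {
    p <- suppressWarnings(
      wilcox.test(errorsA, errorsB, exact = FALSE, correct = TRUE)$p.value)
  }
  list(p_raw = p, p_corrected = min(1, p * cfg$bonferroniM))
}

#' Quadratic severity-versus-error regression
#'
#' Degree-2 least squares of the absolute error on the actual value, plus
#' the Spearman correlation between them.
#'
#' @param actual actual values (severity axis).
#' @param absErrors absolute errors.
#' @return list with `coef` (intercept, linear, quadratic) and
#'   `spearman_rho`.
#' @export
severityErrorRegression <- function(actual, absErrors) {
  stopifnot(length(actual) == length(absErrors))
  if (length(unique(actual)) < 3)
    stop("need at least 3 distinct severity values")
  fit <- lm(absErrors ~ actual + I(actual^2))
  if (anyNA(coef(fit))) stop("rank-deficient design")
  if (sd(absErrors) == 0)
    stop("constant errors: correlation undefined")
  list(coef = unname(coef(fit)),
       spearman_rho = cor(rank(actual), rank(absErrors)))
}

#' Full evaluation report for one grid block
#'
#' Convenience wrapper assembling the block's pairwise RMSE and MAE, the MD
#' MAE, pooled correlations (points and MD), the MD Bland-Altman analysis
#' and severity strata into one list.
#'
#' @param predPoints,labelPoints,maskPoints matrices (pairs x points).
#' @param predMD,actMD,maskMD MD vectors per pair.
#' @param cfg an [evalConfig()].
#' @return an `EvalReport` list.
#' @export
evalReport <- function(predPoints, labelPoints, maskPoints, predMD, actMD,
                       maskMD, cfg = evalConfig()) {
  keepMD <- maskMD == 0
  may <- function(expr) tryCatch(expr, error = function(e) NULL)
  rep <- list(
    rmse = may(pairwiseRMSE(predPoints, labelPoints,
                            maskPoints)[c("mean", "sd")]),
    mae = may(pairwiseMAE(predPoints, labelPoints,
                          maskPoints)[c("mean", "sd")]),
    md_mae = may(list(mean = mean(abs(predMD[keepMD] - actMD[keepMD])),
                      sd = sd(abs(predMD[keepMD] - actMD[keepMD])))),
    cor_points = may(correlations(predPoints, labelPoints, maskPoints)),
    cor_md = may(correlations(predMD[keepMD], actMD[keepMD])),
    bland_altman = may(blandAltman(predMD[keepMD], actMD[keepMD], cfg)),
    severity = may(severityStrata(predPoints, labelPoints, maskPoints,
                                  ifelse(keepMD, actMD, NA), cfg)))
  class(rep) <- "EvalReport"
  rep
}
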