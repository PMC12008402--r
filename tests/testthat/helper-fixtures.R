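# Shared fixtures, built in code.

g24 <- buildGrid("24-2")
g10 <- buildGrid("10-2")
g30 <- buildGrid("30-2")

# an OD 24-2 exam with a given constant threshold
flatExam <- function(value = 30, pattern = "24-2", laterality = "OD",
                     date = "2021-01-01", md = 0, rates = c(0.1, 0.1, 0.1),
                     eyeId = "E1") {
  g <- buildGrid(pattern)
  VFExam("P1", eyeId, laterality, date, pattern,
         rep(value, nPoints(g)), md = md, fpRate = rates[1],
         fnRate = rates[2], flRate = rates[3])
}

# 24-2 exam whose four superior-row nasal means are exactly `means`
# (superior to inferior); other points stay at `base`
nasalMeansExam <- function(means, base = 33) {
  th <- rep(base, 54)
  for (k in 1:4) {
    y <- c(21, 15, 9, 3)[k]
    r <- which(gridPoints(g24)[, 2] == y)
    r <- r[order(gridPoints(g24)[r, 1])][1:3]
    th[r] <- means[k]
  }
  ex <- flatExam()
  ex@thresholds <- th
  ex
}

# series from (date, value) pairs applied at every point
seriesFromValues <- function(dates, values, pattern = "24-2", md = NULL,
                             eyeId = "E1") {
  g <- buildGrid(pattern)
  exams <- mapply(function(d, v, i) {
    e <- flatExam(v, pattern, date = d, eyeId = eyeId)
    e@md <- if (is.null(md)) v - 33 else md[i]
    e
  }, dates, values, seq_along(dates), SIMPLIFY = FALSE)
  VFSeries(exams)
}

coordKey <- function(m) paste(m[, 1], m[, 2])
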