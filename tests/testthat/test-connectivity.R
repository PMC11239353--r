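# FC / ISFC estimators, averaging, edge statistics.

test_that("FC matches the direct Pearson formula and its exact limits", {
  set.seed(1)
  base <- rnorm(20)
  data <- cbind(base, -base + 1e-9 * rnorm(20), rnorm(20), rnorm(20))
  ts <- makeSeries(data)
  w <- windowSchedule(ts)[1, ]
  fc <- connValues(computeFC(ts, w))
  expect_equal(fc[1, 2], -1, tolerance = 1e-6)
  expect_equal(diag(fc), rep(1, 4), ignore_attr = TRUE)
  expect_true(max(abs(fc - t(fc))) < 1e-12)
  expect_true(all(abs(fc) <= 1 + 1e-12))
  # duplicated signal: edge exactly 1
  ts2 <- makeSeries(cbind(base, base, rnorm(20), rnorm(20)))
  expect_equal(connValues(computeFC(ts2, w))[1, 2], 1)
  # brute-force Pearson oracle on a 4-point series
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ts3 <- makeSeries(cbind(x, y),
                    windows = data.frame(label = "W1", state = "ToM",
                                         start = 1L, end = 4L,
                                         description = ""))
  expect_equal(connValues(computeFC(ts3, windowSchedule(ts3)[1, ]))[1, 2],
               oracle)
})

test_that("a zero-variance ROI is reported by name", {
  data <- cbind(rnorm(10), rep(2, 10))
  ts <- makeSeries(data)
  expect_error(computeFC(ts, windowSchedule(ts)[1, ]), "R2")
})

test_that("ISFC equals FC when all subjects share a noiseless signal", {
  set.seed(2)
  shared <- matrix(rnorm(30 * 4), 30, 4)
  tss <- lapply(1:3, function(i) makeSeries(shared, id = paste0("s", i)))
  w <- windowSchedule(tss[[1]])[1, ]
  isfc <- computeISFC(tss, w)
  fc <- computeFC(tss[[1]], w)
  expect_lt(max(abs(connValues(isfc[[1]]) - connValues(fc))), 1e-10)
  expect_equal(diag(connValues(isfc[[2]])), rep(1, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("ISFC of independent noise is centred on zero", {
  set.seed(3)
  tss <- lapply(1:1000, function(i)
    makeSeries(matrix(rnorm(30 * 4), 30, 4), id = paste0("s", i)))
  w <- windowSchedule(tss[[1]])[1, ]
  isfc <- computeISFC(tss, w)
  m <- Reduce(`+`, lapply(isfc, connValues)) / length(isfc)
  expect_lt(abs(mean(m)), 0.02)
})

test_that("ISFC suppresses subject-specific coupling relative to FC", {
  # intrinsic-dominated generator: b >> a
  cfg <- singleGroupConfig(n = 200L, seed = 13, coupling = 0.02,
                           mixWeights = c(a = 0.3, b = 2, c = 0.3))
  coh <- generateCohort(cfg)
  w <- windowSchedule(coh)[1, ]
  nets <- roiNetwork(coh@roiSet)
  it <- nets == "ToM"
  fcs <- lapply(coh@subjects, computeFC, window = w)
  isfcs <- computeISFC(coh@subjects, w)
  off <- function(m) mean(abs(connValues(m)[it, !it]))
  diffs <- vapply(seq_along(fcs), function(i) off(fcs[[i]]) - off(isfcs[[i]]),
                  numeric(1L))
  ht <- t.test(diffs, alternative = "greater")
  expect_lt(ht$p.value, 0.01)
})

test_that("ISFC input validation", {
  ts <- makeSeries(matrix(rnorm(40), 10, 4))
  expect_error(computeISFC(list(ts), windowSchedule(ts)[1, ]),
               ">=2 subjects")
  other <- makeSeries(matrix(rnorm(30), 10, 3), id = "s2")
  expect_error(computeISFC(list(ts, other), windowSchedule(ts)[1, ]),
               "mismatched ROI")
})

test_that("averaging follows the Fisher-z closed form", {
  v1 <- symCorr(4); v2 <- symCorr(4)
  m1 <- makeConn(v1); m2 <- makeConn(v2)
  # single matrix: identity
  expect_equal(connValues(averageMatrices(list(m1))), v1, tolerance = 1e-6)
  # r and -r cancel on the z scale
  mneg <- makeConn(-v1 + 2 * diag(diag(v1)))
  avg <- connValues(averageMatrices(list(m1, mneg)))
  expect_lt(max(abs(avg[upper.tri(avg)])), 1e-10)
  # {0.3, 0.7} closed-form oracle
  a <- diag(2); a[1, 2] <- a[2, 1] <- 0.3
  b <- diag(2); b[1, 2] <- b[2, 1] <- 0.7
  got <- connValues(averageMatrices(list(makeConn(a), makeConn(b))))[1, 2]
  expect_equal(got, tanh((atanh(0.3) + atanh(0.7)) / 2))
  expect_error(averageMatrices(list()), "empty")
})

test_that("edge t-tests: constant edges, FDR null control, guards", {
  v <- diag(4); v[upper.tri(v)] <- 0.8; v <- (v + t(v)) / 2; diag(v) <- 1
  mats <- lapply(1:5, function(i) makeConn(v))
  res <- edgeTTests(mats)
  expect_true(all(res$survives))
  expect_true(all(res$degenerate))
  expect_true(all(res$q >= res$p))
  expect_error(edgeTTests(mats[1:2]), "insufficient")
  # global null: iid mean-zero edges, survivals should be rare
  set.seed(8)
  falsePos <- replicate(60, {
    nul <- lapply(1:20, function(i) makeConn(symCorr(12, scale = 0.1)))
    sum(edgeTTests(nul, alpha = 0.01)$survives)
  })
  expect_lt(mean(falsePos), 0.2)
})

test_that("edge strength classes follow the 0.5 benchmark", {
  expect_equal(classifyEdgeStrength(0.9), "strong")
  expect_equal(classifyEdgeStrength(0.5), "moderate")
  expect_equal(classifyEdgeStrength(-0.2), "weak")
  expect_equal(classifyEdgeStrength(0.56, band = 0.05), "strong")
  expect_equal(classifyEdgeStrength(0.46), "moderate")
})
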