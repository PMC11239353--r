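# Split protocols (subject-level, leakage-free) and the metric suite.

test_that("repeated 80:20 splits have the exact prescribed sizes", {
  sp <- makeSplits(155, "repeated_8020", seed = 1)
  expect_length(sp, 10L)
  for (s in sp) {
    expect_length(s$train, 124L)
    expect_length(s$test, 31L)
    expect_length(intersect(s$train, s$test), 0L)
    expect_setequal(c(s$train, s$test), 1:155)
  }
  # repeats differ
  expect_false(identical(sp[[1]]$train, sp[[2]]$train))
})

test_that("stratified 80:20 keeps every class on both sides", {
  labs <- factor(rep(c("pass", "inconsistent", "fail"), times = c(84, 23, 15)))
  sp <- makeSplits(122, "repeated_8020", seed = 2, labels = labs)
  for (s in sp) {
    expect_length(s$train, 97L)   # floor(0.8 * 122)
    trainTab <- table(labs[s$train])
    testTab <- table(labs[s$test])
    expect_true(all(trainTab >= 1) && all(testTab >= 1))
    # proportions preserved within a couple of subjects
    expect_true(all(abs(trainTab - 0.8 * table(labs)) <= 2))
  }
})

test_that("five folds partition the subjects; leave-one-out is exhaustive", {
  labs <- factor(rep(c("a", "b"), times = c(13, 9)))
  folds <- makeSplits(22, "kfold5", seed = 3, labels = labs)
  expect_length(folds, 5L)
  allTest <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(allTest, 1:22)
  expect_equal(length(allTest), 22L)  # disjoint cover
  for (f in folds)
    expect_length(intersect(f$train, f$test), 0L)
  loo <- makeSplits(10, "loo")
  expect_length(loo, 10L)
  expect_true(all(vapply(loo, function(s) length(s$test), integer(1L)) == 1L))
  expect_setequal(unlist(lapply(loo, `[[`, "test")), 1:10)
  expect_error(makeSplits(4, "kfold5"), ">= 5")
  expect_error(makeSplits(1, "loo"), ">= 2")
})

test_that("metrics match their confusion-matrix identities", {
  perfect <- computeMetrics(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$macro["f1"]), 1)
  # confusion [[40,10],[10,40]] -> accuracy 0.8, F1 0.8
  truth <- rep(c("x", "y"), each = 50)
  pred <- c(rep("x", 40), rep("y", 10), rep("x", 10), rep("y", 40))
  m <- computeMetrics(pred, truth)
  expect_equal(m$accuracy, 0.8)
  expect_equal(unname(m$macro["f1"]), 0.8)
  expect_equal(sum(diag(m$confusion)) / sum(m$confusion), m$accuracy)
  # all-one-class predictions on balanced truth
  m2 <- computeMetrics(rep("x", 100), truth)
  expect_equal(m2$accuracy, 0.5)
  expect_error(computeMetrics(c("a"), c("a", "b")), "length")
})

test_that("score curves are produced with sane AUCs", {
  set.seed(4)
  truth <- rep(c("A", "B"), each = 30)
  scoreA <- c(rnorm(30, 1), rnorm(30, -1))
  scores <- cbind(A = scoreA, B = -scoreA)
  pred <- ifelse(scoreA > 0, "A", "B")
  m <- computeMetrics(pred, truth, scores = scores)
  expect_true(!is.null(m$roc))
  aucs <- unique(m$roc$auc[m$roc$class == "A"])
  expect_gt(aucs, 0.9)
  expect_true(all(m$pr$precision >= 0 & m$pr$precision <= 1))
})

test_that("experiment orchestration reports per-split metrics without leakage", {
  cfg <- experimentConfig(
    cohort = smallCohortConfig(n = 9L, seed = 8),
    featureKind = "FC", model = "stgcnn", scheme = "repeated_8020",
    nRepeats = 2L,
    decoder = decoderConfig(filters = 6L, chebOrder = 1L, epochs = 4L,
                            minEpochs = 4L, batchSize = 16L, seed = 1L),
    seed = 5L)
  rep <- runExperiment(cfg)
  expect_equal(nrow(rep$perRepeat), 2L)
  expect_true(all(rep$perRepeat$accuracy >= 0 & rep$perRepeat$accuracy <= 1))
  expect_equal(rep$meanAccuracy, mean(rep$perRepeat$accuracy))
  expect_s3_class(rep$metrics$perClass, "data.frame")
})

test_that("leave-one-out experiments yield one row per subject", {
  cfg <- experimentConfig(
    cohort = smallCohortConfig(n = 6L, seed = 9),
    featureKind = "FC", model = "stgcnn", scheme = "loo",
    decoder = decoderConfig(filters = 4L, chebOrder = 1L, epochs = 2L,
                            minEpochs = 2L, batchSize = 16L, seed = 1L),
    seed = 6L)
  rep <- runExperiment(cfg)
  expect_equal(nrow(rep$perRepeat), 6L)
})
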