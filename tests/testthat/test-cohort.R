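# Synthetic cohort generator: study-cohort composition, determinism, and
# the statistical structure the downstream stages rely on.

test_that("default configuration reproduces the study cohort composition", {
  coh <- generateCohort(cohortConfig(seed = 1))
  meta <- cohortMeta(coh)
  expect_equal(length(coh), 155L)
  expect_equal(sum(meta$age_group == "child"), 122L)
  expect_equal(sum(meta$age_group == "adult"), 33L)
  child <- meta[meta$age_group == "child", ]
  expect_equal(as.vector(table(child$group)[c("pass", "fail", "inconsistent")]),
               c(84L, 15L, 23L))
  # behavioral score ranges per group
  expect_true(all(child$n_correct[child$group == "pass"] %in% 5:6))
  expect_true(all(child$n_correct[child$group == "inconsistent"] %in% 3:4))
  expect_true(all(child$n_correct[child$group == "fail"] %in% 0:2))
  expect_true(all(is.na(meta$n_correct[meta$age_group == "adult"])))
  # series dimensions: 168 time points x 12 ROIs
  expect_equal(dim(boldData(coh[[1]])), c(168L, 12L))
})

test_that("the cohort is a pure function of its configuration", {
  c1 <- generateCohort(smallCohortConfig(seed = 42))
  c2 <- generateCohort(smallCohortConfig(seed = 42))
  expect_identical(cohortMeta(c1), cohortMeta(c2))
  expect_identical(boldData(c1[[3]]), boldData(c2[[3]]))
  c3 <- generateCohort(smallCohortConfig(seed = 43))
  expect_false(identical(boldData(c1[[3]]), boldData(c3[[3]])))
})

test_that("default windows: 10 events, 5 per state, 168 TRs, all >= 5", {
  w <- defaultWindows()
  expect_equal(nrow(w), 10L)
  expect_equal(as.vector(table(w$state)[c("ToM", "Pain")]), c(5L, 5L))
  lens <- w$end - w$start + 1L
  expect_equal(sum(lens), 168L)
  expect_true(all(lens >= 5L))
  # windows tile the series
  expect_equal(w$start, c(1L, head(w$end, -1L) + 1L))
})

test_that("default ROI set has 6 ToM and 6 Pain regions", {
  rs <- defaultRoiSet()
  nets <- roiNetwork(rs)
  expect_equal(as.vector(table(nets)[c("ToM", "Pain")]), c(6L, 6L))
  expect_false(anyDuplicated(roiNames(rs)) > 0)
})

test_that("noise-only signals carry no mean connectivity", {
  # a = b = 0: pure white noise, coupling target at the baseline (0)
  cfg <- singleGroupConfig(n = 1000L, seed = 7, coupling = 0,
                           mixWeights = c(a = 0, b = 0, c = 1))
  coh <- generateCohort(cfg)
  w1 <- windowSchedule(coh)[1, ]
  offdiag <- vapply(coh@subjects, function(ts) {
    v <- connValues(computeFC(ts, w1))
    mean(v[upper.tri(v)])
  }, numeric(1L))
  expect_lt(abs(mean(offdiag)), 0.02)
})

test_that("with only the shared component, subjects are stimulus-locked", {
  cfg <- singleGroupConfig(n = 3L, seed = 5, coupling = 0,
                           mixWeights = c(a = 1, b = 0, c = 0))
  coh <- generateCohort(cfg)
  for (pair in list(c(1, 2), c(2, 3)))
    expect_gt(cor(boldData(coh[[pair[1]]])[, 1],
                  boldData(coh[[pair[2]]])[, 1]), 1 - 1e-9)
})

test_that("group coupling targets are recovered within 0.05", {
  cfg <- cohortConfig(nSubjects = 150L,
                      groupSizes = c(pass = 50L, inconsistent = 50L,
                                     fail = 50L),
                      ageGroups = c(child = 150L, adult = 0L), seed = 3)
  coh <- generateCohort(cfg)
  nets <- roiNetwork(coh@roiSet)
  it <- nets == "ToM"
  conns <- subjectMeanConnectivity(coh, "FC")
  between <- vapply(conns, function(m) mean(connValues(m)[it, !it]),
                    numeric(1L))
  grp <- cohortMeta(coh)$group
  for (g in c("pass", "inconsistent", "fail"))
    expect_lt(abs(mean(between[grp == g]) - cfg$groupCoupling[[g]]), 0.05)
})

test_that("the engaged network is more coherent in its own windows", {
  cfg <- singleGroupConfig(n = 40L, seed = 9, coupling = 0.2)
  coh <- generateCohort(cfg)
  w <- windowSchedule(coh)
  nets <- roiNetwork(coh@roiSet)
  it <- nets == "ToM"
  withinToM <- function(state) {
    rows <- which(w$state == state)
    mean(vapply(coh@subjects, function(ts) {
      mean(vapply(rows, function(i) {
        v <- connValues(computeFC(ts, w[i, ]))[it, it]
        mean(v[upper.tri(v)])
      }, numeric(1L)))
    }, numeric(1L)))
  }
  expect_gt(withinToM("ToM"), withinToM("Pain"))
})

test_that("invalid configurations fail with informative errors", {
  expect_error(cohortConfig(nSubjects = 10,
                            groupSizes = c(pass = 4, inconsistent = 3,
                                           fail = 2),
                            ageGroups = c(child = 10, adult = 0)),
               "group sizes")
  expect_error(cohortConfig(nSubjects = 4,
                            groupSizes = c(pass = 4, inconsistent = 0,
                                           fail = 0),
                            ageGroups = c(child = 4, adult = 1)),
               "age group")
  badCov <- diag(12); badCov[1, 2] <- badCov[2, 1] <- 2  # not PSD
  expect_error(cohortConfig(stateCovariances = list(ToM = badCov,
                                                    Pain = diag(12))),
               "positive semi-definite")
  expect_error(generateCohort(singleGroupConfig(n = 4, coupling = -0.5,
                              mixWeights = c(a = 1, b = 0.6, c = 0.4))),
               "below the baseline")
})
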