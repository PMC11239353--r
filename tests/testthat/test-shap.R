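# Shapley attribution: game-theoretic axioms, the permutation oracle,
# sampling convergence, ROI aggregation.

test_that("exact values satisfy additivity, symmetry, dummy, efficiency", {
  # additive game: phi_i = c_i
  cvec <- c(2, -1, 0.5)
  att <- shapExact(function(s) sum(cvec[s]), 3)
  expect_equal(unname(shapValues(att)), cvec)
  # symmetry: exchangeable features get equal phi
  sym <- shapExact(function(s) as.numeric(sum(s) >= 1), 3)
  expect_equal(diff(range(shapValues(sym))), 0)
  # dummy: a feature with no marginal contribution gets 0
  dummy <- shapExact(function(s) as.numeric(s[1]), 3)
  expect_equal(unname(shapValues(dummy))[2:3], c(0, 0))
  # efficiency on a random value table
  set.seed(1)
  tab <- rnorm(2^4)
  vf <- function(s) tab[sum(2^(which(s) - 1)) + 1]
  a4 <- shapExact(vf, 4)
  expect_lt(abs(sum(shapValues(a4)) - (a4@fullValue - a4@baseline)), 1e-8)
})

test_that("exact values equal the permutation-average formulation", {
  set.seed(2)
  tab <- rnorm(8)
  vf <- function(s) tab[sum(2^(which(s) - 1)) + 1]
  got <- shapValues(shapExact(vf, 3))
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  oracle <- numeric(3)
  for (p in seq_len(nrow(perms))) {
    s <- rep(FALSE, 3); prev <- vf(s)
    for (i in perms[p, ]) {
      s[i] <- TRUE
      cur <- vf(s)
      oracle[i] <- oracle[i] + (cur - prev) / nrow(perms)
      prev <- cur
    }
  }
  expect_equal(unname(got), oracle, tolerance = 1e-12)
})

test_that("sampled values converge to exact within 3 standard errors", {
  set.seed(3)
  tab <- rnorm(2^6)
  vf <- function(s) tab[sum(2^(which(s) - 1)) + 1]
  exact <- shapValues(shapExact(vf, 6))
  samp <- shapSample(vf, 6, nPermutations = 400, seed = 9)
  dev <- abs(shapValues(samp) - exact) / pmax(samp@se, 1e-12)
  expect_true(all(dev <= 3))
  # determinism and guards
  s2 <- shapSample(vf, 6, nPermutations = 400, seed = 9)
  expect_identical(shapValues(samp), shapValues(s2))
  expect_error(shapExact(vf, 17), "shapSample")
  expect_error(shapSample(vf, 6, nPermutations = 10), "50")
})

test_that("masked value functions impute the background", {
  predictFn <- function(v) sum(v * c(1, 10, 100))
  vf <- maskedValueFn(predictFn, x = c(1, 1, 1), background = c(0, 0, 0))
  expect_equal(vf(c(TRUE, FALSE, TRUE)), 101)
  expect_equal(vf(rep(FALSE, 3)), 0)
})

test_that("ROI ranking recovers planted signal and breaks ties stably", {
  rois <- paste0("R", 1:4)
  nets <- c("ToM", "ToM", "Pain", "Pain")
  mk <- function(phi) new("ShapAttribution", phi = setNames(phi, rois),
                          se = numeric(4), baseline = 0, fullValue = sum(phi),
                          method = "exact")
  planted <- lapply(1:5, function(i) mk(c(5, 0.1, 0.1, 0.1) + rnorm(4, 0, 0.01)))
  rk <- rankRois(planted, rois, nets)
  expect_equal(rk$roi[1], "R1")
  # all-zero attributions: ranks tied, order = ROI-table order
  zero <- rankRois(list(mk(rep(0, 4))), rois, nets)
  expect_equal(zero$roi, rois)
  # edge-level features aggregate to both endpoints
  edgePhi <- setNames(c(3, 0.1, 0.1), c("R1--R2", "R2--R3", "R3--R4"))
  edgeAtt <- new("ShapAttribution", phi = edgePhi, se = numeric(3),
                 baseline = 0, fullValue = sum(edgePhi), method = "exact")
  rkE <- rankRois(list(edgeAtt), rois, nets)
  expect_true(all(c("R1", "R2") %in% rkE$roi[1:2]))
  # top-per-network flags: 12 ROIs, 3 ToM + 3 Pain dominant
  rois12 <- roiNames(defaultRoiSet())
  nets12 <- unname(roiNetwork(defaultRoiSet()))
  att12 <- new("ShapAttribution",
               phi = setNames(seq(0.1, 1.2, length.out = 12), rois12),
               se = numeric(12), baseline = 0, fullValue = 1,
               method = "exact")
  rk12 <- rankRois(list(att12), rois12, nets12)
  expect_equal(sum(rk12$dominant), 6L)
  expect_equal(as.vector(table(rk12$network[rk12$dominant])[c("ToM", "Pain")]),
               c(3L, 3L))
  expect_error(rankRois(list(), rois), "empty")
})
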