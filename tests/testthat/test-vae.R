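# Convolutional VAE: architecture shape algebra, closed-form terms, exact
# gradients, training behavior, and the latent group classifier.

test_that("parameter counts match the printed architecture row by row", {
  enc <- vaeParamCount(vaeConfig(), "encoder")
  dec <- vaeParamCount(vaeConfig(), "decoder")
  expect_equal(enc$params[enc$layer == "conv2d_1"], 320L)
  expect_equal(enc$params[enc$layer == "conv2d_2"], 18496L)
  expect_equal(enc$params[enc$layer == "dense"], 18464L)
  expect_equal(enc$params[enc$layer == "z_mean"], 1056L)
  expect_equal(enc$params[enc$layer == "z_log_var"], 1056L)
  expect_equal(attr(enc, "total"), 39392L)
  expect_equal(dec$params[dec$layer == "dense"], 19008L)
  expect_equal(dec$params[dec$layer == "conv2d_transpose_1"], 36928L)
  expect_equal(dec$params[dec$layer == "conv2d_transpose_2"], 18464L)
  expect_equal(dec$params[dec$layer == "decoder_output"], 289L)
  expect_equal(attr(dec, "total"), 74689L)
  # encoder spatial maps: 12 -> 6 -> 3
  expect_equal(enc$output_shape[enc$layer == "conv2d_1"], "(6, 6, 32)")
  expect_equal(enc$output_shape[enc$layer == "conv2d_2"], "(3, 3, 64)")
  # actual tensors agree with the declared counts
  m <- buildVae(vaeConfig())
  nPar <- function(nms) sum(vapply(m@params[nms], length, numeric(1L)))
  expect_equal(nPar(c("Wc1", "bc1", "Wc2", "bc2", "Wd1", "bd1", "Wmu",
                      "bmu", "Wlv", "blv")), 39392)
  expect_equal(nPar(c("Wdd", "bdd", "Wu1", "bu1", "Wu2", "bu2", "Wout",
                      "bout")), 74689)
})

test_that("ROI-subset geometries (12, 8, 6) encode and reconstruct", {
  for (n in c(12L, 8L, 6L)) {
    m <- buildVae(vaeConfig(nRoi = n, seed = 2))
    x <- symCorr(n)
    enc <- vaeEncode(m, x)
    expect_equal(dim(enc$mu), c(1L, 32L))
    expect_equal(dim(vaeReconstruct(m, x)[[1]]), c(n, n))
  }
  m <- buildVae(vaeConfig(nRoi = 8L))
  expect_error(vaeEncode(m, symCorr(12)), "shape error")
})

test_that("closed-form latent terms: KL and the reparameterization", {
  expect_equal(klTerm(0, 0), 0)
  expect_equal(klTerm(1, 0), 0.5)
  expect_gte(klTerm(rnorm(5), rnorm(5)), 0)
  # quadrature oracle for a random 1-d case
  set.seed(3)
  mu <- rnorm(1); lv <- rnorm(1); s2 <- exp(lv)
  dens <- function(x) dnorm(x, mu, sqrt(s2)) *
    (dnorm(x, mu, sqrt(s2), log = TRUE) - dnorm(x, log = TRUE))
  oracle <- integrate(dens, mu - 10 * sqrt(s2), mu + 10 * sqrt(s2))$value
  expect_equal(klTerm(mu, lv), oracle, tolerance = 1e-4)
  # z = mu when the variance vanishes; seeded draws reproduce
  expect_equal(reparameterize(c(1, 2), c(-1e10, -1e10), seed = 1), c(1, 2))
  expect_identical(reparameterize(0:1, c(0, 0), seed = 5),
                   reparameterize(0:1, c(0, 0), seed = 5))
  set.seed(4)
  z <- replicate(1e5, 0 + exp(0 / 2) * rnorm(1))
  expect_lt(abs(var(z) - 1), 0.02)
})

test_that("loss components are additive and match their definitions", {
  x <- symCorr(4)
  l0 <- vaeLoss(x, x, rep(0, 3), rep(0, 3))
  expect_equal(l0$total, 0)
  l1 <- vaeLoss(x, x + 1, rep(0, 3), rep(0, 3))
  expect_equal(l1$reconstruction, 1)
  set.seed(5)
  mu <- rnorm(4); lv <- rnorm(4); xr <- symCorr(4)
  l <- vaeLoss(x, xr, mu, lv)
  expect_equal(l$total, l$reconstruction + l$kl)
  expect_equal(l$reconstruction, mean((x - xr)^2))
  expect_equal(l$kl, klTerm(mu, lv))
  lsum <- vaeLoss(x, xr, mu, lv, reduction = "sum")
  expect_equal(lsum$reconstruction, 16 * l$reconstruction)
})

test_that("VAE gradients match finite differences", {
  cfg <- vaeConfig(nRoi = 6L, seed = 8)
  m <- buildVae(cfg)
  params <- m@params; maps <- m@maps
  x <- fcdecode:::vaeInput(symCorr(6))
  eps <- rnorm(cfg$latentDim)
  lossAt <- function(p) {
    enc <- fcdecode:::vaeEncodeOne(p, maps, x, withCache = TRUE)
    z <- enc$mu + exp(enc$lv / 2) * eps
    dec <- fcdecode:::vaeDecodeOne(p, maps, z, withCache = TRUE)
    sum((dec$cache$xr - x)^2) + 0.5 * sum(enc$mu^2 + exp(enc$lv) - 1 - enc$lv)
  }
  enc <- fcdecode:::vaeEncodeOne(params, maps, x, withCache = TRUE)
  z <- enc$mu + exp(enc$lv / 2) * eps
  dec <- fcdecode:::vaeDecodeOne(params, maps, z, withCache = TRUE)
  gr <- fcdecode:::vaeBackwardOne(params, maps, enc, z, eps, dec, x)
  set.seed(10)
  for (nm in c("Wc1", "Wc2", "bd1", "Wmu", "blv", "Wdd", "Wu1", "Wu2",
               "Wout", "bout")) {
    i <- sample(length(params[[nm]]), 1)
    h <- 1e-6
    up <- params; up[[nm]][i] <- up[[nm]][i] + h
    dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
    num <- (lossAt(up) - lossAt(dn)) / (2 * h)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-3,
                 label = paste("gradient of", nm))
  }
})

test_that("training is deterministic, shrinks constant-data loss, guards", {
  mats <- lapply(1:6, function(i) symCorr(6))
  cfg <- vaeConfig(nRoi = 6L, epochs = 5L, seed = 3)
  v1 <- suppressWarnings(trainVae(mats, cfg))
  v2 <- suppressWarnings(trainVae(mats, cfg))
  expect_identical(v1@history, v2@history)
  expect_equal(nrow(v1@history), 5L)
  # constant dataset: reconstruction shrinks by at least half
  const <- lapply(1:6, function(i) mats[[1]])
  vc <- suppressWarnings(trainVae(const, vaeConfig(nRoi = 6L, epochs = 150L,
                                                   seed = 4)))
  expect_lt(tail(vc@history$reconstruction, 1),
            0.5 * vc@history$reconstruction[1])
  expect_error(trainVae(list(), vaeConfig()), "empty")
  expect_warning(trainVae(mats, vaeConfig(nRoi = 6L, epochs = 1L)),
                 "batch size")
})

test_that("a zero-weight encoder returns its biases", {
  m <- buildVae(vaeConfig(nRoi = 6L, seed = 2))
  p <- m@params
  for (nm in grep("^W", names(p), value = TRUE)) p[[nm]][] <- 0
  p$bmu <- rnorm(32)
  m@params <- p
  enc <- vaeEncode(m, symCorr(6))
  expect_equal(drop(enc$mu), p$bmu)
  expect_equal(drop(enc$logVar), rep(0, 32))
})

test_that("latent classifier: tie-break, chance under shuffling", {
  # zero-weight head: all sigmoid outputs equal -> lowest group index
  clf <- new("LatentClassifier", weights = matrix(0, 4, 3),
             bias = rep(0, 3), center = rep(0, 4), scale = rep(1, 4),
             classes = c("pass", "inconsistent", "fail"),
             history = data.frame())
  pr <- predictGroup(clf, matrix(rnorm(12), 3, 4))
  expect_true(all(pr == "pass"))
  # shuffled labels give about the majority-class rate
  set.seed(6)
  z <- matrix(rnorm(90 * 8), 90, 8)
  labs <- factor(rep(c("pass", "inconsistent", "fail"), times = c(60, 18, 12)))
  shuffled <- sample(labs)
  fit <- trainGroupClassifier(z[1:60, ], shuffled[1:60], seed = 2)
  acc <- mean(predictGroup(fit, z[61:90, ]) == shuffled[61:90])
  expect_lt(abs(acc - 60 / 90), 0.25)
  expect_error(trainGroupClassifier(z, rep("pass", 90)), ">= 2")
})
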