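# Graph-convolutional decoder: exact gradients, a hand-rolled forward
# oracle, loss identities, determinism and learning sanity.

tinyDecoderData <- function(nGraphs = 6L, n = 4L, f = 3L, seed = 42L) {
  set.seed(seed)
  graphs <- lapply(seq_len(nGraphs), function(i)
    randomGraph(n, features = matrix(rnorm(n * f), n, f)))
  list(graphs = graphs,
       labels = factor(rep(c("A", "B"), length.out = nGraphs)))
}

test_that("backpropagated gradients match finite differences", {
  d <- tinyDecoderData()
  config <- decoderConfig(filters = c(5L, 4L), chebOrder = 2L, dropout = 0,
                          batchSize = 6L, epochs = 1L, seed = 3L)
  data <- fcdecode:::decoderDataset(d$graphs, d$labels, config)
  set.seed(9)
  params <- fcdecode:::initDecoderParams(config, 3L, 4L)
  running <- fcdecode:::initRunningStats(config)
  oneHot <- matrix(0, 6, 2)
  oneHot[cbind(1:6, as.integer(d$labels))] <- 1
  lossAt <- function(p) {
    fw <- fcdecode:::decoderForwardPass(p, running, config, data, 1:6,
                                        training = TRUE)
    fcdecode:::crossEntropy(fw$probs, oneHot)
  }
  fw <- fcdecode:::decoderForwardPass(params, running, config, data, 1:6,
                                      training = TRUE)
  gr <- fcdecode:::decoderBackwardPass(fw, params, config, data, 1:6, oneHot)
  set.seed(11)
  for (nm in c("W1_0", "W1_2", "W2_1", "b1", "b2", "gamma1", "beta2",
               "Wd", "bd")) {
    i <- sample(length(params[[nm]]), 1)
    eps <- 1e-6
    up <- params; up[[nm]][i] <- up[[nm]][i] + eps
    dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
    num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("the forward pass reproduces a step-by-step matrix computation", {
  set.seed(7)
  n <- 4L; f <- 3L; nF <- 4L
  g <- randomGraph(n, features = matrix(rnorm(n * f), n, f))
  config <- decoderConfig(filters = nF, chebOrder = 1L, dropout = 0.65,
                          seed = 1L)
  W0 <- matrix(rnorm(f * nF), f, nF)
  W1 <- matrix(rnorm(f * nF), f, nF)
  b <- matrix(rnorm(n * nF), n, nF)
  Wd <- matrix(rnorm(2L * nF * 2L), 2L * nF, 2L)
  bd <- c(0.3, -0.2)
  params <- list(W1_0 = W0, W1_1 = W1, b1 = b,
                 gamma1 = rep(1, nF), beta1 = rep(0, nF), Wd = Wd, bd = bd)
  model <- new("DecoderModel", config = unclass(config),
               params = list(weights = params,
                             running = fcdecode:::initRunningStats(config),
                             nNode = n, nFeat = f),
               history = data.frame(), classes = c("A", "B"),
               trained = TRUE)
  probs <- decoderForward(model, list(g))
  # independent computation: Chebyshev conv -> BN(stats 0/1) -> ReLU ->
  # pairwise max-pool -> flatten -> dense -> softmax
  X <- nodeFeatures(g)
  Tk <- chebBasis(g, 1L)
  Z <- Tk$T0 %*% X %*% W0 + Tk$T1 %*% X %*% W1 + b
  Z <- Z / sqrt(1 + 1e-5)              # inference BN with init stats
  Z <- pmax(Z, 0)
  P <- pmax(Z[c(1, 3), ], Z[c(2, 4), ])
  logits <- as.vector(P) %*% Wd + matrix(bd, 1)
  oracle <- exp(logits - max(logits)); oracle <- oracle / sum(oracle)
  expect_equal(drop(probs), drop(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(probs), 1, tolerance = 1e-6)
})

test_that("loss identities: perfect, uniform, and the L2 penalty", {
  perfect <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(decoderLoss(perfect, c(1L, 2L)), 0, tolerance = 1e-9)
  uniform <- matrix(0.5, 2, 2)
  expect_equal(decoderLoss(uniform, c(1L, 2L)), log(2))
  # epsilon clamping keeps the loss finite
  expect_true(is.finite(decoderLoss(matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
                                    c(1L, 2L))))
  # penalty equals the direct sum-of-squares computation
  d <- tinyDecoderData(nGraphs = 4L)
  m <- suppressWarnings(trainDecoder(d$graphs, d$labels,
    decoderConfig(filters = 3L, chebOrder = 1L, epochs = 2L, minEpochs = 1L,
                  valEvery = 1L, batchSize = 4L, seed = 2L)))
  ws <- m@params$weights
  wNames <- grep("^W", names(ws), value = TRUE)
  ssq <- sum(vapply(wNames, function(nm) sum(ws[[nm]]^2), numeric(1L)))
  nP <- sum(vapply(names(ws), function(nm) length(ws[[nm]]), numeric(1L)))
  rho <- 0.1
  expect_equal(decoderLoss(uniform, c(1L, 2L), m, rho),
               log(2) + rho / (2 * nP) * ssq)
})

test_that("training is deterministic under the seed and actually learns", {
  coh <- generateCohort(smallCohortConfig(n = 9L, seed = 6))
  ds <- stateDataset(coh, "FC")
  cfg <- decoderConfig(filters = c(8L), chebOrder = 2L, epochs = 8L,
                       minEpochs = 8L, batchSize = 16L, seed = 7L)
  m1 <- suppressWarnings(trainDecoder(ds$graphs, ds$states, cfg))
  m2 <- suppressWarnings(trainDecoder(ds$graphs, ds$states, cfg))
  expect_identical(m1@params$weights, m2@params$weights)
  expect_identical(m1@history, m2@history)
  expect_lt(tail(m1@history$train_loss, 1), m1@history$train_loss[1])
  pr <- predictState(m1, ds$graphs[1:5])
  expect_length(pr$labels, 5L)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-6))
  expect_true(all(pr$probs > 0 & pr$probs < 1))
})

test_that("degenerate training inputs are rejected", {
  d <- tinyDecoderData()
  expect_error(trainDecoder(d$graphs, rep("A", 6),
                            decoderConfig(filters = 4L)),
               "at least 2 classes")
  expect_error(trainDecoder(d$graphs, d$labels,
                            decoderConfig(filters = 4L, nClasses = 3L)),
               "nClasses")
  untrained <- new("DecoderModel", config = list(), params = list(),
                   history = data.frame(), classes = "A", trained = FALSE)
  expect_error(predictState(untrained, d$graphs), "not trained")
})
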