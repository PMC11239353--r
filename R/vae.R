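# Convolutional variational autoencoder over N x N connectivity matrices,
# plus the latent-space performance-group classifier.
#
# Encoder: two stride-2 SAME 3x3 convolutions (1 -> 32 -> 64 channels),
# flatten, dense 32 (ReLU), then linear heads for the latent mean and
# log-variance.  Decoder: dense back to the coarse grid, two transposed
# stride-2 convolutions mirroring the encoder geometry (64 -> 64 -> 32),
# and a stride-1 output convolution with sigmoid activation.  For the
# default 12 x 12 input the spatial sizes are 12 -> 6 -> 3 -> 6 -> 12 and
# the parameter counts are 39,392 (encoder) and 74,689 (decoder).
# Correlation inputs are mapped from [-1, 1] to [0, 1] before encoding so
# the sigmoid output can represent them.

#' VAE configuration
#'
#' Defaults are the published recipe: kernel 3, 32 base filters (doubling
#' in the second encoder layer), stride 2, SAME padding, 50 epochs, latent
#' dimension 32, one input channel, batch size 128 for autoencoder
#' training and 32 for prediction.
#'
#' @param nRoi input matrix side length (12, 8 or 6 in the ROI-subset
#'   analyses; any side >= 4 works).
#' @param kernel,filters,strides,latentDim,channels architecture numbers.
#' @param epochs training epochs.
#' @param batchTrain,batchPredict batch sizes.
#' @param learningRate Adam learning rate.
#' @param klWarmup number of initial epochs over which the KL term is
#'   annealed linearly from 0 to full weight.  At 12 x 12 inputs the KL
#'   term otherwise overwhelms the reconstruction term early in training
#'   and the posterior collapses to the prior (an uninformative latent
#'   space); warm-up is the standard mitigation.
#' @param freeBits per-dimension KL floor in nats: latent dimensions
#'   whose KL is already below this budget receive no KL gradient, the
#'   free-bits guard against full posterior collapse.
#' @param seed integer seed.
#' @return configuration list of class `"VaeConfig"`.
#' @export
vaeConfig <- function(nRoi = 12L, kernel = 3L, filters = 32L, strides = 2L,
                      epochs = 50L, latentDim = 32L, channels = 1L,
                      batchTrain = 128L, batchPredict = 32L,
                      learningRate = 0.001, klWarmup = ceiling(epochs * 0.3),
                      freeBits = 0.25, seed = 1L) {
  stopifnot(nRoi >= 4L, kernel == 3L, strides == 2L, channels == 1L)
  structure(list(nRoi = as.integer(nRoi), kernel = as.integer(kernel),
                 filters = as.integer(filters), strides = as.integer(strides),
                 epochs = as.integer(epochs), latentDim = as.integer(latentDim),
                 channels = as.integer(channels),
                 batchTrain = as.integer(batchTrain),
                 batchPredict = as.integer(batchPredict),
                 padding = "SAME", learningRate = learningRate,
                 klWarmup = as.integer(klWarmup), freeBits = freeBits,
                 seed = as.integer(seed)),
            class = "VaeConfig")
}

vaeMaps <- function(config) {
  n <- config$nRoi
  m1 <- convMap(n, n, config$strides)
  m2 <- convMap(m1$outH, m1$outW, config$strides)
  m0 <- convMap(n, n, 1L)
  list(m1 = m1, m2 = m2, m0 = m0,
       flat = m2$nOut * (2L * config$filters))
}

#' Build an (untrained) VAE with freshly initialized parameters
#'
#' @param config a [vaeConfig()].
#' @return a [VaeModel-class].
#' @export
buildVae <- function(config = vaeConfig()) {
  set.seed(substreamSeed(config$seed, "vae-init"))
  maps <- vaeMaps(config)
  f1 <- config$filters; f2 <- 2L * config$filters
  ld <- config$latentDim
  k2 <- config$kernel^2
  params <- list(
    Wc1 = glorot(k2 * 1L, f1, c(k2 * 1L, f1)), bc1 = rep(0, f1),
    Wc2 = glorot(k2 * f1, f2, c(k2 * f1, f2)), bc2 = rep(0, f2),
    Wd1 = glorot(maps$flat, ld), bd1 = rep(0, ld),
    Wmu = glorot(ld, ld), bmu = rep(0, ld),
    Wlv = glorot(ld, ld), blv = rep(0, ld),
    Wdd = glorot(ld, maps$flat), bdd = rep(0, maps$flat),
    Wu1 = glorot(k2 * f2, f2, c(k2 * f2, f2)), bu1 = rep(0, f2),
    Wu2 = glorot(k2 * f1, f2, c(k2 * f1, f2)), bu2 = rep(0, f1),
    Wout = glorot(k2 * f1, 1L, c(k2 * f1, 1L)), bout = 0)
  new("VaeModel", config = unclass(config), params = params, maps = maps,
      history = data.frame(), trained = FALSE)
}

#' Per-layer and total trainable parameter counts
#'
#' Computed from the shape algebra (convolution: k*k*Cin*Cout + Cout;
#' dense: Fin*Fout + Fout).  For the default 12 x 12 geometry the encoder
#' totals 39,392 and the decoder 74,689 trainable parameters.
#'
#' @param model a [VaeModel-class] (or a [vaeConfig()]).
#' @param part `"encoder"` or `"decoder"`.
#' @return data.frame with columns `layer`, `output_shape`, `params`, and
#'   a `"total"` attribute; `sum(x$params)` equals the total.
#' @export
#' @examples
#' sum(vaeParamCount(vaeConfig(), "encoder")$params)  # 39392
vaeParamCount <- function(model, part = c("encoder", "decoder")) {
  part <- match.arg(part)
  config <- if (is(model, "VaeModel")) model@config else unclass(model)
  maps <- vaeMaps(if (is(model, "VaeModel")) structure(config, class = "VaeConfig")
                  else model)
  k2 <- config$kernel^2
  f1 <- config$filters; f2 <- 2L * config$filters
  ld <- config$latentDim
  shp <- function(m, ch) paste0("(", m$outH, ", ", m$outW, ", ", ch, ")")
  tab <- if (part == "encoder") {
    data.frame(
      layer = c("encoder_input", "conv2d_1", "conv2d_2", "flatten",
                "dense", "z_mean", "z_log_var"),
      output_shape = c(paste0("(", config$nRoi, ", ", config$nRoi, ", 1)"),
                       shp(maps$m1, f1), shp(maps$m2, f2),
                       paste0("(", maps$flat, ")"), paste0("(", ld, ")"),
                       paste0("(", ld, ")"), paste0("(", ld, ")")),
      params = c(0L, k2 * 1L * f1 + f1, k2 * f1 * f2 + f2, 0L,
                 maps$flat * ld + ld, ld * ld + ld, ld * ld + ld))
  } else {
    data.frame(
      layer = c("z_sampling", "dense", "reshape", "conv2d_transpose_1",
                "conv2d_transpose_2", "decoder_output"),
      output_shape = c(paste0("(", ld, ")"), paste0("(", maps$flat, ")"),
                       shp(maps$m2, f2), shp(maps$m1, f2),
                       paste0("(", config$nRoi, ", ", config$nRoi, ", ", f1, ")"),
                       paste0("(", config$nRoi, ", ", config$nRoi, ", 1)")),
      params = c(0L, ld * maps$flat + maps$flat, 0L,
                 k2 * f2 * f2 + f2, k2 * f2 * f1 + f1, k2 * f1 * 1L + 1L))
  }
  attr(tab, "total") <- sum(tab$params)
  tab
}

# Map correlation matrices to [0, 1] column vectors (positions x channels).
vaeInput <- function(x) {
  if (is(x, "ConnectivityMatrix")) x <- connValues(x)
  matrix((as.vector(x) + 1) / 2, ncol = 1L)
}

vaeEncodeOne <- function(params, maps, x, withCache = FALSE) {
  c1 <- convFwd(x, params$Wc1, params$bc1, maps$m1)
  r1 <- reluFwd(c1$y)
  c2 <- convFwd(r1$y, params$Wc2, params$bc2, maps$m2)
  r2 <- reluFwd(c2$y)
  flat <- matrix(as.vector(r2$y), 1L)
  d1 <- flat %*% params$Wd1 + params$bd1
  rh <- reluFwd(d1)
  mu <- drop(rh$y %*% params$Wmu + params$bmu)
  lv <- drop(rh$y %*% params$Wlv + params$blv)
  out <- list(mu = mu, lv = lv)
  if (withCache)
    out$cache <- list(x = x, c1 = c1, r1 = r1, c2 = c2, r2 = r2,
                      flat = flat, rh = rh)
  out
}

vaeDecodeOne <- function(params, maps, z, withCache = FALSE) {
  f2 <- ncol(params$Wu1)
  g <- matrix(z, 1L) %*% params$Wdd + params$bdd
  rg <- reluFwd(g)
  G <- matrix(as.vector(rg$y), maps$m2$nOut, f2)
  u1 <- convTransposeFwd(G, params$Wu1, params$bu1, maps$m2, f2)
  ru1 <- reluFwd(u1)
  u2 <- convTransposeFwd(ru1$y, params$Wu2, params$bu2, maps$m1,
                         length(params$bu2))
  ru2 <- reluFwd(u2)
  oc <- convFwd(ru2$y, params$Wout, params$bout, maps$m0)
  xr <- sigmoid(oc$y)
  out <- list(xr = xr)
  if (withCache)
    out$cache <- list(z = z, rg = rg, G = G, ru1 = ru1, ru2 = ru2,
                      oc = oc, xr = xr)
  out
}

#' Encode connectivity matrices to latent mean and log-variance
#'
#' @param model a [VaeModel-class].
#' @param x a [ConnectivityMatrix-class], an N x N matrix, or a list of
#'   either.
#' @return list with matrices `mu` and `logVar` (one row per input).
#' @export
vaeEncode <- function(model, x) {
  if (!is.list(x)) x <- list(x)
  n <- model@config$nRoi
  enc <- lapply(x, function(xi) {
    v <- vaeInput(xi)
    if (nrow(v) != n * n)
      stop("shape error: expected ", n, " x ", n, " input", call. = FALSE)
    vaeEncodeOne(model@params, model@maps, v)
  })
  list(mu = do.call(rbind, lapply(enc, `[[`, "mu")),
       logVar = do.call(rbind, lapply(enc, `[[`, "lv")))
}

#' Reconstruct connectivity matrices through the latent mean
#'
#' @param model a [VaeModel-class].
#' @param x input as in [vaeEncode()].
#' @return list of reconstructed matrices on the correlation scale.
#' @export
vaeReconstruct <- function(model, x) {
  if (!is.list(x)) x <- list(x)
  n <- model@config$nRoi
  lapply(x, function(xi) {
    enc <- vaeEncodeOne(model@params, model@maps, vaeInput(xi))
    dec <- vaeDecodeOne(model@params, model@maps, enc$mu)
    matrix(dec$xr * 2 - 1, n, n)
  })
}

#' Reparameterization: sample z from the latent Gaussian
#'
#' \eqn{z = \mu + \exp(\log\sigma^2 / 2) \epsilon}, \eqn{\epsilon \sim N(0, 1)},
#' drawn from a seeded stream.
#'
#' @param mu,logVar equal-length numeric vectors.
#' @param seed optional integer seed (uses the current RNG stream when NULL).
#' @return numeric vector z.
#' @export
reparameterize <- function(mu, logVar, seed = NULL) {
  stopifnot(length(mu) == length(logVar))
  if (!is.null(seed)) set.seed(substreamSeed(seed, "reparam"))
  mu + exp(logVar / 2) * rnorm(length(mu))
}

#' Closed-form KL divergence to the standard normal prior
#'
#' \eqn{\frac{1}{2} \sum_j (\mu_j^2 + \sigma_j^2 - 1 - \log \sigma_j^2)};
#' always >= 0, zero iff mu = 0 and logVar = 0.  For a matrix input the
#' mean of the per-row divergences is returned.
#'
#' @param mu,logVar latent mean and log-variance (vectors or matrices).
#' @return scalar.
#' @export
#' @examples
#' klTerm(1, 0)  # 0.5
klTerm <- function(mu, logVar) {
  mu <- rbind(mu); logVar <- rbind(logVar)
  mean(0.5 * rowSums(mu^2 + exp(logVar) - 1 - logVar))
}

#' VAE loss components
#'
#' Reconstruction is the mean squared error over matrix entries
#' (`reduction = "mean"`) or its sum over entries (`reduction = "sum"`,
#' the scaling used for training so the reconstruction and KL terms are
#' commensurate); the total is reconstruction + KL.
#'
#' @param x,xRecon original and reconstructed matrices (matching shape).
#' @param mu,logVar latent statistics.
#' @param reduction `"mean"` or `"sum"`.
#' @return list with `reconstruction`, `kl`, `total`.
#' @export
vaeLoss <- function(x, xRecon, mu, logVar, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (is(x, "ConnectivityMatrix")) x <- connValues(x)
  if (is(xRecon, "ConnectivityMatrix")) xRecon <- connValues(xRecon)
  stopifnot(length(x) == length(xRecon))
  mse <- mean((as.numeric(x) - as.numeric(xRecon))^2)
  recon <- if (reduction == "sum") mse * length(x) else mse
  kl <- klTerm(mu, logVar)
  list(reconstruction = recon, kl = kl, total = recon + kl)
}

# Backward pass for one sample; returns gradient list matching params.
# klWeight scales the KL-derived gradient (warm-up annealing).
vaeBackwardOne <- function(params, maps, enc, z, eps, dec, x,
                           klWeight = 1, freeBits = 0) {
  g <- list()
  nE <- nrow(x)
  # reconstruction: sum over entries of (xr - x)^2
  dOut <- 2 * (dec$cache$xr - x) * dec$cache$xr * (1 - dec$cache$xr)
  cb <- convBwd(dOut, dec$cache$oc, params$Wout, maps$m0,
                length(params$bu2))
  g$Wout <- cb$dW; g$bout <- cb$db
  dRu2 <- reluBwd(cb$dx, dec$cache$ru2)
  tb <- convTransposeBwd(dRu2, dec$cache$ru1$y, params$Wu2, maps$m1)
  g$Wu2 <- tb$dW; g$bu2 <- tb$db
  dRu1 <- reluBwd(tb$dx, dec$cache$ru1)
  tb1 <- convTransposeBwd(dRu1, dec$cache$G, params$Wu1, maps$m2)
  g$Wu1 <- tb1$dW; g$bu1 <- tb1$db
  dG <- matrix(as.vector(tb1$dx), 1L)
  dG <- reluBwd(dG, dec$cache$rg)
  g$Wdd <- base::crossprod(matrix(z, 1L), dG)
  g$bdd <- drop(dG)
  dz <- drop(dG %*% base::t(params$Wdd))
  # KL gradients (annealed, with a per-dimension free-bits floor: a
  # dimension already within its information budget is not pushed
  # further toward the prior) plus the reparameterized path
  klDim <- 0.5 * (enc$mu^2 + exp(enc$lv) - 1 - enc$lv)
  klMask <- as.numeric(klDim > freeBits)
  dmu <- klWeight * klMask * enc$mu + dz
  dlv <- klWeight * klMask * 0.5 * (exp(enc$lv) - 1) +
    dz * eps * 0.5 * exp(enc$lv / 2)
  h <- enc$cache$rh$y
  g$Wmu <- base::crossprod(h, matrix(dmu, 1L)); g$bmu <- dmu
  g$Wlv <- base::crossprod(h, matrix(dlv, 1L)); g$blv <- dlv
  dh <- matrix(dmu, 1L) %*% base::t(params$Wmu) +
    matrix(dlv, 1L) %*% base::t(params$Wlv)
  dh <- reluBwd(dh, enc$cache$rh)
  g$Wd1 <- base::crossprod(enc$cache$flat, dh)
  g$bd1 <- drop(dh)
  dflat <- dh %*% base::t(params$Wd1)
  dR2 <- matrix(as.vector(dflat), maps$m2$nOut, ncol(params$Wc2))
  dR2 <- reluBwd(dR2, enc$cache$r2)
  cb2 <- convBwd(dR2, enc$cache$c2, params$Wc2, maps$m2, ncol(params$Wc1))
  g$Wc2 <- cb2$dW; g$bc2 <- cb2$db
  dR1 <- reluBwd(cb2$dx, enc$cache$r1)
  cb1 <- convBwd(dR1, enc$cache$c1, params$Wc1, maps$m1, 1L)
  g$Wc1 <- cb1$dW; g$bc1 <- cb1$db
  g
}

#' Train the convolutional VAE
#'
#' Adam on the summed-reconstruction + KL objective for `config$epochs`
#' epochs.  Deterministic under `config$seed`.  Datasets smaller than the
#' training batch size are allowed (one full batch per epoch) with a
#' warning.
#'
#' @param matrices list of [ConnectivityMatrix-class] (or plain N x N
#'   matrices on the correlation scale).
#' @param config a [vaeConfig()].
#' @return a trained [VaeModel-class]; `@history` has per-epoch
#'   `reconstruction` (mean MSE per entry), `kl` and `total`.
#' @export
trainVae <- function(matrices, config = vaeConfig()) {
  if (!length(matrices)) stop("empty dataset", call. = FALSE)
  if (length(matrices) < config$batchTrain)
    warning("fewer samples (", length(matrices), ") than the training ",
            "batch size (", config$batchTrain, "); using one batch per epoch")
  model <- buildVae(config)
  set.seed(substreamSeed(config$seed, "vae-train"))
  maps <- model@maps
  params <- model@params
  xs <- lapply(matrices, vaeInput)
  if (any(vapply(xs, nrow, integer(1L)) != config$nRoi^2))
    stop("shape error: all matrices must be ", config$nRoi, " x ",
         config$nRoi, call. = FALSE)
  nS <- length(xs)
  state <- adamInit(params)
  hist <- data.frame()
  warmup <- max(0L, config$klWarmup %||% 0L)
  for (ep in seq_len(config$epochs)) {
    klW <- if (warmup > 0L) min(1, ep / warmup) else 1
    ord <- sample.int(nS)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchTrain))
    epRec <- 0; epKl <- 0
    for (bi in batches) {
      grads <- NULL
      for (s in bi) {
        enc <- vaeEncodeOne(params, maps, xs[[s]], withCache = TRUE)
        eps <- rnorm(config$latentDim)
        z <- enc$mu + exp(enc$lv / 2) * eps
        dec <- vaeDecodeOne(params, maps, z, withCache = TRUE)
        gs <- vaeBackwardOne(params, maps, enc, z, eps, dec, xs[[s]],
                             klWeight = klW,
                             freeBits = config$freeBits %||% 0)
        grads <- if (is.null(grads)) gs else
          Map(`+`, grads, gs)
        epRec <- epRec + mean((dec$cache$xr - xs[[s]])^2)
        epKl <- epKl + 0.5 * sum(enc$mu^2 + exp(enc$lv) - 1 - enc$lv)
      }
      grads <- lapply(grads, `/`, length(bi))
      upd <- adamStep(params, grads, state, lr = config$learningRate)
      params <- upd$params
      state <- upd$state
    }
    hist <- rbind(hist, data.frame(
      epoch = ep, reconstruction = epRec / nS, kl = epKl / nS,
      total = (epRec * config$nRoi^2 + epKl) / nS))
  }
  new("VaeModel", config = unclass(config), params = params, maps = maps,
      history = hist, trained = TRUE)
}

#' Train the latent-space performance-group classifier
#'
#' A dense one-vs-all sigmoid head on (standardized) latent codes, trained
#' with one-hot binary cross-entropy by Adam for 50 epochs; predicted
#' group is the argmax of the sigmoid outputs (ties resolve to the lowest
#' group index).
#'
#' @param z latent-code matrix (one row per subject), e.g. `vaeEncode()$mu`.
#' @param labels performance group per row (pass / inconsistent / fail).
#' @param epochs,batchSize,learningRate,seed training controls.
#' @return a [LatentClassifier-class].
#' @export
trainGroupClassifier <- function(z, labels, epochs = 50L, batchSize = 32L,
                                 learningRate = 0.01, seed = 1L) {
  z <- as.matrix(z)
  labels <- factor(labels)
  classes <- levels(labels)
  if (length(classes) < 2L)
    stop("need >= 2 performance groups", call. = FALSE)
  set.seed(substreamSeed(seed, "group-clf"))
  ctr <- colMeans(z)
  scl <- apply(z, 2L, sd); scl[scl == 0] <- 1
  zs <- scale(z, center = ctr, scale = scl)
  y <- matrix(0, nrow(z), length(classes))
  y[cbind(seq_len(nrow(z)), as.integer(labels))] <- 1
  params <- list(W = glorot(ncol(z), length(classes)),
                 b = rep(0, length(classes)))
  state <- adamInit(params)
  hist <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(zs))
    batches <- split(ord, ceiling(seq_along(ord) / batchSize))
    epLoss <- 0
    for (bi in batches) {
      zb <- zs[bi, , drop = FALSE]
      yb <- y[bi, , drop = FALSE]
      s <- sigmoid(sweep(zb %*% params$W, 2L, params$b, `+`))
      epLoss <- epLoss - sum(yb * log(pmax(s, 1e-12)) +
                               (1 - yb) * log(pmax(1 - s, 1e-12)))
      dS <- (s - yb) / (nrow(zb) * ncol(yb))
      grads <- list(W = base::crossprod(zb, dS), b = colSums(dS))
      upd <- adamStep(params, grads, state, lr = learningRate)
      params <- upd$params
      state <- upd$state
    }
    hist <- rbind(hist, data.frame(epoch = ep,
                                   bce = epLoss / (nrow(zs) * ncol(y))))
  }
  new("LatentClassifier", weights = params$W, bias = params$b,
      center = ctr, scale = scl, classes = classes, history = hist)
}

#' Predict performance group from latent codes
#'
#' @param classifier a [LatentClassifier-class].
#' @param z latent-code matrix.
#' @return factor of predicted groups.
#' @export
predictGroup <- function(classifier, z) {
  zs <- scale(as.matrix(z), center = classifier@center,
              scale = classifier@scale)
  s <- sigmoid(sweep(zs %*% classifier@weights, 2L, classifier@bias, `+`))
  idx <- max.col(s, ties.method = "first")
  factor(classifier@classes[idx], levels = classifier@classes)
}
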