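# Graph-convolutional state decoder.
#
# Each block applies a K-order Chebyshev spectral filter (sum_k T_k(L~) H W_k
# plus a per-node bias), batch normalization, ReLU, pairwise node max-pooling
# (size 2 over the fixed ROI ordering) and dropout.  After the last block the
# node features are flattened into a dense softmax head.  Pooling levels use
# a coarsened graph: pooled adjacency aggregates the pairwise edge weights,
# from which the normalized Laplacian and Chebyshev operators are rebuilt.

#' Decoder configuration
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 0.001, dropout 0.65, weight decay 0, early-stopping patience 3, up to
#' 100 epochs, two output classes.  `filters` sets the stack depth and
#' filter schedule (`c(16)`, `c(16, 32)` or `c(16, 32, 64)`).
#'
#' @param filters integer vector of per-block filter counts (length = depth).
#' @param chebOrder Chebyshev polynomial order K (>= 1).
#' @param dropout dropout rate applied after each block.
#' @param learningRate Adam learning rate.
#' @param weightDecay L2 penalty rate (rho in the loss).
#' @param patience early-stopping patience: training stops after
#'   `patience` consecutive validation checks without improvement, with
#'   the best weights seen restored.
#' @param valEvery validation-check cadence in epochs.  Under heavy
#'   dropout the loss trajectory is strongly non-monotone, so the monitor
#'   is evaluated every few epochs rather than every epoch.
#' @param minEpochs burn-in before early stopping engages.
#' @param batchSize minibatch size (16, 32 or 64 in the study protocol).
#' @param epochs maximum training epochs.
#' @param nClasses number of output classes.
#' @param clipNorm global gradient-norm clip threshold (stabilizes the
#'   heavy-dropout minibatch noise); `Inf` disables clipping.
#' @param valFraction fraction of the training set held out (stratified)
#'   for early stopping.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @return configuration list of class `"DecoderConfig"`.
#' @export
decoderConfig <- function(filters = c(16L, 32L, 64L), chebOrder = 3L,
                          dropout = 0.65, learningRate = 0.001,
                          weightDecay = 0, patience = 3L, batchSize = 32L,
                          epochs = 100L, nClasses = 2L, valFraction = 0.1,
                          minEpochs = max(10L, epochs %/% 5L),
                          valEvery = 5L, clipNorm = 1, seed = 1L) {
  stopifnot(length(filters) >= 1L, all(filters >= 1L), chebOrder >= 1L,
            dropout >= 0, dropout < 1, batchSize >= 1L, nClasses >= 2L)
  structure(list(filters = as.integer(filters),
                 chebOrder = as.integer(chebOrder), dropout = dropout,
                 learningRate = learningRate, weightDecay = weightDecay,
                 patience = as.integer(patience),
                 minEpochs = as.integer(minEpochs),
                 valEvery = as.integer(valEvery), clipNorm = clipNorm,
                 batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), nClasses = as.integer(nClasses),
                 valFraction = valFraction, seed = as.integer(seed)),
            class = "DecoderConfig")
}

# Normalized Laplacian with silent degree regularization (pooled graphs).
normLaplacianScaled <- function(adj, epsilon = 1e-6) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  deg[deg <= 0] <- epsilon
  dInv <- 1 / sqrt(deg)
  lap <- diag(n) - dInv * base::t(dInv * adj)
  lap <- (lap + base::t(lap)) / 2
  lmax <- max(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  (2 / lmax) * lap - diag(n)
}

poolAdjacency <- function(adj) {
  n <- nrow(adj)
  n2 <- ceiling(n / 2)
  groups <- lapply(seq_len(n2), function(p) intersect(c(2 * p - 1, 2 * p),
                                                      seq_len(n)))
  a2 <- matrix(0, n2, n2)
  for (p in seq_len(n2)) for (q in seq_len(n2))
    a2[p, q] <- sum(adj[groups[[p]], groups[[q]]])
  diag(a2) <- 0
  a2
}

# Per-sample Chebyshev operator stacks (flattened, for fast sparse
# block-diagonal assembly) for every pooling level.
sampleOperators <- function(graph, K, depth) {
  adj <- adjacency(graph)
  lt <- scaledLaplacian(graph)
  levels <- vector("list", depth)
  for (l in seq_len(depth)) {
    terms <- chebBasis(lt, K)
    levels[[l]] <- list(n = nrow(lt),
                        x = lapply(terms, as.vector))
    if (l < depth) {
      adj <- poolAdjacency(adj)
      lt <- normLaplacianScaled(adj)
    }
  }
  levels
}

# Assemble the dataset: operators per level, stacked features, labels.
decoderDataset <- function(graphs, labels, config) {
  depth <- length(config$filters)
  K <- config$chebOrder
  nNode <- nrow(adjacency(graphs[[1]]))
  feats <- lapply(graphs, nodeFeatures)
  if (length(unique(vapply(feats, ncol, integer(1L)))) != 1L)
    stop("shape error: graphs differ in node-feature width", call. = FALSE)
  ops <- lapply(graphs, sampleOperators, K = K, depth = depth)
  dims <- integer(depth)
  n <- nNode
  for (l in seq_len(depth)) { dims[l] <- n; n <- ceiling(n / 2) }
  list(ops = ops, feats = feats, labels = labels, nNode = nNode,
       dims = dims, nFlat = n * config$filters[depth], K = K, depth = depth)
}

# Sparse block-diagonal Chebyshev operator for a batch at one level/order.
batchOperator <- function(data, batchIdx, level, k) {
  n <- data$dims[level]
  iT <- rep(seq_len(n), n)
  jT <- rep(seq_len(n), each = n)
  B <- length(batchIdx)
  off <- rep((seq_len(B) - 1L) * n, each = n * n)
  xs <- unlist(lapply(data$ops[batchIdx],
                      function(o) o[[level]]$x[[k]]), use.names = FALSE)
  sparseMatrix(i = rep(iT, B) + off, j = rep(jT, B) + off, x = xs,
               dims = c(B * n, B * n))
}

poolIndices <- function(B, n) {
  n2 <- ceiling(n / 2)
  aLoc <- 2 * seq_len(n2) - 1L
  bLoc <- 2 * seq_len(n2)
  off <- rep((seq_len(B) - 1L) * n, each = n2)
  a <- rep(aLoc, B) + off
  b <- rep(pmin(bLoc, n), B) + off     # odd tail: b == a (passthrough)
  list(a = a, b = b, n2 = n2)
}

initDecoderParams <- function(config, nFeat, nNode) {
  K <- config$chebOrder
  params <- list()
  fIn <- nFeat
  n <- nNode
  for (l in seq_along(config$filters)) {
    fOut <- config$filters[l]
    for (k in 0:K)
      params[[paste0("W", l, "_", k)]] <-
        glorot(fIn * (K + 1L), fOut, c(fIn, fOut))
    params[[paste0("b", l)]] <- matrix(0, n, fOut)
    params[[paste0("gamma", l)]] <- rep(1, fOut)
    params[[paste0("beta", l)]] <- rep(0, fOut)
    fIn <- fOut
    n <- ceiling(n / 2)
  }
  params$Wd <- glorot(n * fIn, config$nClasses)
  params$bd <- rep(0, config$nClasses)
  params
}

initRunningStats <- function(config) {
  lapply(config$filters, function(f) list(mean = rep(0, f), var = rep(1, f)))
}

# Full forward pass over a batch.  Returns probabilities plus caches
# needed for the backward pass.
#
# `collect = TRUE` runs a batch-norm re-estimation pass: dropout off,
# batch statistics computed exactly over the given samples (momentum 0).
# Statistics collected during dropout-active minibatches do not match the
# dropout-free activation distribution seen at inference, so evaluation
# always uses re-estimated statistics.
decoderForwardPass <- function(params, running, config, data, batchIdx,
                               training = FALSE, collect = FALSE) {
  B <- length(batchIdx)
  K <- config$chebOrder
  depth <- data$depth
  dropRate <- if (collect) 0 else config$dropout
  bnTrain <- training || collect
  momentum <- if (collect) 0 else 0.9
  H <- do.call(rbind, data$feats[batchIdx])
  caches <- vector("list", depth)
  for (l in seq_len(depth)) {
    n <- data$dims[l]
    ops <- lapply(0:K, function(k) batchOperator(data, batchIdx, l, k + 1L))
    M <- lapply(ops, function(S) as.matrix(S %*% H))
    Z <- Reduce(`+`, lapply(0:K, function(k)
      M[[k + 1L]] %*% params[[paste0("W", l, "_", k)]]))
    Z <- Z + params[[paste0("b", l)]][rep(seq_len(n), B), , drop = FALSE]
    bn <- bnFwd(Z, params[[paste0("gamma", l)]], params[[paste0("beta", l)]],
                running[[l]], bnTrain, momentum = momentum)
    if (bnTrain) running[[l]] <- bn$running
    rl <- reluFwd(bn$y)
    pi <- poolIndices(B, n)
    hA <- rl$y[pi$a, , drop = FALSE]
    hB <- rl$y[pi$b, , drop = FALSE]
    maskA <- hA >= hB
    P <- pmax(hA, hB)
    dp <- dropoutFwd(P, dropRate, training)
    caches[[l]] <- list(ops = ops, M = M, bn = bn$cache, relu = rl,
                        pool = pi, maskA = maskA, drop = dp, n = n, B = B)
    H <- dp$y
  }
  nL <- data$dims[depth]
  nL2 <- ceiling(nL / 2)
  fL <- config$filters[depth]
  A <- array(H, dim = c(nL2, B, fL))
  Xflat <- base::t(matrix(aperm(A, c(1L, 3L, 2L)), nL2 * fL, B))
  logits <- sweep(Xflat %*% params$Wd, 2L, params$bd, `+`)
  probs <- softmaxRows(logits)
  list(probs = probs, logits = logits, Xflat = Xflat, caches = caches,
       running = running, H = H)
}

decoderBackwardPass <- function(fw, params, config, data, batchIdx, oneHot) {
  B <- length(batchIdx)
  K <- config$chebOrder
  depth <- data$depth
  grads <- list()
  dLogits <- (fw$probs - oneHot) / B
  grads$Wd <- base::crossprod(fw$Xflat, dLogits)
  grads$bd <- colSums(dLogits)
  dXflat <- dLogits %*% base::t(params$Wd)
  nL2 <- ceiling(data$dims[depth] / 2)
  fL <- config$filters[depth]
  dA <- aperm(array(base::t(dXflat), dim = c(nL2, fL, B)), c(1L, 3L, 2L))
  dH <- matrix(dA, nL2 * B, fL)
  for (l in rev(seq_len(depth))) {
    cc <- fw$caches[[l]]
    dP <- dropoutBwd(dH, cc$drop)
    dhA <- dP * cc$maskA
    dhB <- dP * (!cc$maskA)
    dRelu <- matrix(0, cc$n * B, ncol(dP))
    # scatter-add pooled gradients; a/b indices can coincide on odd tails
    dRelu[cc$pool$a, ] <- dRelu[cc$pool$a, , drop = FALSE] + dhA
    dRelu[cc$pool$b, ] <- dRelu[cc$pool$b, , drop = FALSE] + dhB
    dZbn <- reluBwd(dRelu, cc$relu)
    bb <- bnBwd(dZbn, cc$bn)
    grads[[paste0("gamma", l)]] <- bb$dgamma
    grads[[paste0("beta", l)]] <- bb$dbeta
    dZ <- bb$dx
    grads[[paste0("b", l)]] <- rowsum(dZ, rep(seq_len(cc$n), B))
    dHprev <- 0
    for (k in 0:K) {
      W <- params[[paste0("W", l, "_", k)]]
      grads[[paste0("W", l, "_", k)]] <- base::crossprod(cc$M[[k + 1L]], dZ)
      dM <- dZ %*% base::t(W)
      dHprev <- dHprev + as.matrix(cc$ops[[k + 1L]] %*% dM)
    }
    dH <- dHprev
  }
  grads
}

#' Forward pass: class probabilities for a batch of graphs
#'
#' @param model a [DecoderModel-class].
#' @param graphs list of [BrainGraph-class] sharing the model's node count
#'   and feature width.
#' @return matrix of class probabilities, one row per graph (rows sum to 1).
#' @export
decoderForward <- function(model, graphs) {
  config <- model@config
  data <- decoderDataset(graphs, NULL, config)
  if (data$nNode != model@params$nNode)
    stop("shape error: model expects ", model@params$nNode, " nodes, got ",
         data$nNode, call. = FALSE)
  fw <- decoderForwardPass(model@params$weights, model@params$running,
                           config, data, seq_along(graphs),
                           training = FALSE)
  colnames(fw$probs) <- model@classes
  fw$probs
}

#' Decoder loss: cross-entropy plus optional L2 penalty
#'
#' \eqn{-\sum_i y_i \log \hat y_i} averaged over the batch, plus
#' \eqn{(\rho / 2 N_P) \lVert W \rVert^2} where \eqn{N_P} is the number of
#' trainable weights.  Probabilities are epsilon-clamped (1e-12) so the
#' loss is never NaN.
#'
#' @param probs probability rows.
#' @param targets one-hot matrix (or class-index vector).
#' @param model optional [DecoderModel-class] supplying the weights for
#'   the penalty term.
#' @param rho weight-decay rate.
#' @return scalar loss.
#' @export
decoderLoss <- function(probs, targets, model = NULL, rho = 0) {
  probs <- as.matrix(probs)
  if (is.vector(targets) || is.factor(targets)) {
    idx <- as.integer(targets)
    targets <- matrix(0, nrow(probs), ncol(probs))
    targets[cbind(seq_len(nrow(probs)), idx)] <- 1
  }
  loss <- crossEntropy(probs, targets)
  if (!is.null(model) && rho > 0) {
    ws <- model@params$weights
    wNames <- grep("^W", names(ws), value = TRUE)
    ssq <- sum(vnapply(wNames, function(nm) sum(ws[[nm]]^2)))
    nP <- sum(vnapply(names(ws), function(nm) length(ws[[nm]])))
    loss <- loss + rho / (2 * nP) * ssq
  }
  loss
}

#' Train the graph-convolutional state decoder
#'
#' Adam optimization of the cross-entropy loss with stratified
#' early-stopping validation (fraction `valFraction` of the training
#' data, patience on validation loss, best weights restored).  Fully
#' deterministic under `config$seed`.
#'
#' @param graphs list of [BrainGraph-class] with node features.
#' @param labels class label per graph (2 classes for state decoding).
#' @param config a [decoderConfig()].
#' @return a trained [DecoderModel-class]; `@history` holds per-epoch
#'   train/validation loss.
#' @export
trainDecoder <- function(graphs, labels, config = decoderConfig()) {
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (length(classes) < 2L)
    stop("training requires at least 2 classes", call. = FALSE)
  if (length(classes) != config$nClasses)
    stop("config error: nClasses = ", config$nClasses, " but data has ",
         length(classes), call. = FALSE)
  if (length(graphs) < 2L * config$batchSize)
    warning("dataset smaller than twice the batch size")
  set.seed(substreamSeed(config$seed, "decoder-train"))
  data <- decoderDataset(graphs, labels, config)
  nFeat <- ncol(data$feats[[1]])
  params <- initDecoderParams(config, nFeat, data$nNode)
  running <- initRunningStats(config)
  state <- adamInit(params)

  # stratified validation split for early stopping
  y <- as.integer(labels)
  valIdx <- unlist(lapply(seq_along(classes), function(cl) {
    idx <- which(y == cl)
    nVal <- max(1L, round(config$valFraction * length(idx)))
    sample(idx, nVal)
  }))
  trainIdx <- setdiff(seq_along(graphs), valIdx)

  oneHotAll <- matrix(0, length(graphs), config$nClasses)
  oneHotAll[cbind(seq_along(y), y)] <- 1

  nP <- sum(vnapply(names(params), function(nm) length(params[[nm]])))
  wdRate <- if (config$weightDecay > 0) config$weightDecay / nP else 0

  best <- list(loss = Inf, params = params, running = running, epoch = 0L)
  bad <- 0L
  valEvery <- max(1L, config$valEvery %||% 1L)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (ep in seq_len(config$epochs)) {
    ord <- sample(trainIdx)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    epLoss <- 0
    for (bi in batches) {
      fw <- decoderForwardPass(params, running, config, data, bi,
                               training = TRUE)
      running <- fw$running
      grads <- decoderBackwardPass(fw, params, config, data, bi,
                                   oneHotAll[bi, , drop = FALSE])
      grads <- clipGrads(grads, config$clipNorm)
      upd <- adamStep(params, grads, state, lr = config$learningRate,
                      weightDecay = wdRate)
      params <- upd$params
      state <- upd$state
      epLoss <- epLoss + crossEntropy(fw$probs, oneHotAll[bi, , drop = FALSE]) *
        length(bi)
    }
    epLoss <- epLoss / length(trainIdx)
    isCheck <- ep %% valEvery == 0L || ep == config$epochs
    valLoss <- NA_real_
    if (isCheck) {
      # re-estimate batch-norm statistics (dropout off) before evaluating
      runEval <- decoderForwardPass(params, running, config, data,
                                    trainIdx, collect = TRUE)$running
      vw <- decoderForwardPass(params, runEval, config, data, valIdx,
                               training = FALSE)
      valLoss <- crossEntropy(vw$probs, oneHotAll[valIdx, , drop = FALSE])
    }
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = epLoss,
                                   val_loss = valLoss))
    if (isCheck) {
      if (valLoss < best$loss - 1e-6) {
        best <- list(loss = valLoss, params = params, running = runEval,
                     epoch = ep)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (ep >= (config$minEpochs %||% 0L) && bad >= config$patience)
          break
      }
    }
  }
  new("DecoderModel", config = unclass(config),
      params = list(weights = best$params, running = best$running,
                    nNode = data$nNode, nFeat = nFeat),
      history = hist, classes = classes, trained = TRUE)
}

#' Predict cognitive state for a batch of graphs
#'
#' Argmax of the softmax probabilities; exact ties resolve to the lower
#' class index.
#'
#' @param model a trained [DecoderModel-class].
#' @param graphs list of [BrainGraph-class].
#' @return list with `labels` (factor) and `probs` (matrix).
#' @export
predictState <- function(model, graphs) {
  if (!model@trained) stop("model is not trained", call. = FALSE)
  probs <- decoderForward(model, graphs)
  idx <- max.col(probs, ties.method = "first")
  list(labels = factor(model@classes[idx], levels = model@classes),
       probs = probs)
}
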