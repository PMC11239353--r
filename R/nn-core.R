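# Shared neural-network primitives: Adam, batch normalization, ReLU,
# dropout, softmax/cross-entropy, and index-map based 2D convolution
# (forward and adjoint) for the small fixed geometries used here.
# Parameters and gradients are flat named lists of numeric arrays.

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamStep <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weightDecay > 0) g <- g + weightDecay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Global gradient-norm clipping: rescales all gradients jointly so their
# overall L2 norm does not exceed maxNorm (stabilizes noisy minibatches).
clipGrads <- function(grads, maxNorm) {
  if (is.null(maxNorm) || !is.finite(maxNorm) || maxNorm <= 0) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
  if (total > maxNorm) grads <- lapply(grads, `*`, maxNorm / total)
  grads
}

glorot <- function(nIn, nOut, shape = c(nIn, nOut)) {
  lim <- sqrt(6 / (nIn + nOut))
  array(runif(prod(shape), -lim, lim), dim = shape)
}

reluFwd <- function(x) list(y = pmax(x, 0), mask = x > 0)
reluBwd <- function(dy, cache) dy * cache$mask

dropoutFwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (matrix(runif(length(x)), nrow(x)) >= rate) / (1 - rate)
  list(y = x * mask, mask = mask)
}
dropoutBwd <- function(dy, cache) if (is.null(cache$mask)) dy else dy * cache$mask

# Batch normalization over rows (one column = one feature).
bnFwd <- function(x, gamma, beta, running, training, momentum = 0.9,
                  eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    running$mean <- momentum * running$mean + (1 - momentum) * mu
    running$var <- momentum * running$var + (1 - momentum) * v
  } else {
    mu <- running$mean; v <- running$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2L, mu), 2L, istd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(y = y, cache = list(xhat = xhat, istd = istd, gamma = gamma),
       running = running)
}

bnBwd <- function(dy, cache) {
  m <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  t1 <- sweep(dy, 2L, dbeta / m)
  t2 <- sweep(cache$xhat, 2L, dgamma / m, `*`)
  dx <- sweep(t1 - t2, 2L, cache$gamma * cache$istd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmaxRows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}

# Cross-entropy of probability rows against one-hot targets, with
# epsilon clamping so a zero probability never produces NaN.
crossEntropy <- function(probs, oneHot, eps = 1e-12) {
  -mean(rowSums(oneHot * log(pmax(probs, eps))))
}

# ---- 2D convolution via precomputed index maps --------------------------
# Spatial positions are column-major linear indices over (row, col);
# channels are columns of the activation matrix (positions x channels).

#' @noRd
convMap <- function(inH, inW, stride, k = 3L) {
  outH <- as.integer(ceiling(inH / stride))
  outW <- as.integer(ceiling(inW / stride))
  padH <- max((outH - 1L) * stride + k - inH, 0L)
  padW <- max((outW - 1L) * stride + k - inW, 0L)
  padTop <- padH %/% 2L
  padLeft <- padW %/% 2L
  nOut <- outH * outW
  idx <- matrix(0L, nOut, k * k)
  for (co in seq_len(outW)) for (ro in seq_len(outH)) {
    o <- (co - 1L) * outH + ro
    r0 <- (ro - 1L) * stride - padTop
    c0 <- (co - 1L) * stride - padLeft
    tap <- 0L
    for (dc in 0:(k - 1L)) for (dr in 0:(k - 1L)) {
      tap <- tap + 1L
      r <- r0 + dr + 1L; cl <- c0 + dc + 1L
      if (r >= 1L && r <= inH && cl >= 1L && cl <= inW)
        idx[o, tap] <- (cl - 1L) * inH + r
    }
  }
  list(inH = inH, inW = inW, outH = outH, outW = outW, k = k,
       nIn = inH * inW, nOut = nOut, idx = idx)
}

# Gather: x (nIn x C) -> (nOut x k^2*C); padded taps read a zero row.
im2col <- function(x, map) {
  xp <- rbind(0, x)
  nTap <- ncol(map$idx)
  cols <- vector("list", nTap)
  for (t in seq_len(nTap)) cols[[t]] <- xp[map$idx[, t] + 1L, , drop = FALSE]
  do.call(cbind, cols)
}

# Scatter-add adjoint of im2col: (nOut x k^2*C) -> (nIn x C).
col2im <- function(z, map, nChan) {
  out <- matrix(0, map$nIn, nChan)
  nTap <- ncol(map$idx)
  for (t in seq_len(nTap)) {
    rows <- map$idx[, t]
    keep <- rows > 0L          # drop padding taps; kept rows are unique
    if (!any(keep)) next
    block <- z[keep, ((t - 1L) * nChan + 1L):(t * nChan), drop = FALSE]
    out[rows[keep], ] <- out[rows[keep], , drop = FALSE] + block
  }
  out
}

# Strided conv: x (nIn x Cin) -> (nOut x Cout); W ((k^2*Cin) x Cout).
convFwd <- function(x, W, b, map) {
  xcol <- im2col(x, map)
  list(y = sweep(xcol %*% W, 2L, b, `+`), xcol = xcol)
}

convBwd <- function(dy, cache, W, map, nChanIn) {
  list(dW = base::crossprod(cache$xcol, dy), db = colSums(dy),
       dx = col2im(dy %*% base::t(W), map, nChanIn))
}

# Transposed conv (small -> big), the adjoint of the conv described by
# `map` (big -> small).  W has shape ((k^2*Cbig) x Csmall).
convTransposeFwd <- function(x, W, b, map, nChanOut) {
  y <- col2im(x %*% base::t(W), map, nChanOut)
  sweep(y, 2L, b, `+`)
}

convTransposeBwd <- function(dy, x, W, map) {
  dycol <- im2col(dy, map)
  list(dx = dycol %*% W, dW = base::crossprod(dycol, x), db = colSums(dy))
}
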