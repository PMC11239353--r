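# Random-walk node embeddings (node2vec and walklets) trained with a
# skip-gram / negative-sampling objective.  Graphs here are tiny (a dozen
# nodes), so a plain, deterministic R implementation is adequate.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Weighted random walks.  secondOrder enables node2vec (p, q) biases.
randomWalks <- function(adj, walkLength, walksPerNode, p = 1, q = 1,
                        secondOrder = TRUE) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] > 0))
  walks <- list()
  for (start in seq_len(n)) {
    for (w in seq_len(walksPerNode)) {
      walk <- integer(walkLength)
      walk[1] <- start
      for (step in 2:walkLength) {
        cur <- walk[step - 1L]
        nb <- nbrs[[cur]]
        if (!length(nb)) { walk <- walk[seq_len(step - 1L)]; break }
        wts <- adj[cur, nb]
        if (secondOrder && step > 2L) {
          prev <- walk[step - 2L]
          bias <- ifelse(nb == prev, 1 / p,
                         ifelse(adj[prev, nb] > 0, 1, 1 / q))
          wts <- wts * bias
        }
        walk[step] <- nb[sample.int(length(nb), 1L, prob = wts)]
      }
      walks[[length(walks) + 1L]] <- walk
    }
  }
  walks
}

# Skip-gram with negative sampling over (center, context) pairs.
trainSkipGram <- function(pairs, nNodes, dimensions, epochs = 2L,
                          learningRate = 0.025, negatives = 5L) {
  U <- matrix((runif(nNodes * dimensions) - 0.5) / dimensions,
              nNodes, dimensions)
  V <- matrix(0, nNodes, dimensions)
  if (!nrow(pairs)) return(U)
  total <- nrow(pairs) * epochs
  done <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(pairs))
    for (i in ord) {
      lr <- learningRate * max(1e-4, 1 - done / total)
      cn <- pairs[i, 1L]
      targets <- c(pairs[i, 2L], sample.int(nNodes, negatives, replace = TRUE))
      y <- c(1, numeric(negatives))
      g <- (sigmoid(drop(V[targets, , drop = FALSE] %*% U[cn, ])) - y) * lr
      uOld <- U[cn, ]
      U[cn, ] <- uOld - drop(base::crossprod(V[targets, , drop = FALSE], g))
      V[targets, ] <- V[targets, , drop = FALSE] - outer(g, uOld)
      done <- done + 1L
    }
  }
  U
}

contextPairs <- function(walks, window) {
  out <- vector("list", length(walks))
  for (w in seq_along(walks)) {
    walk <- walks[[w]]
    L <- length(walk)
    if (L < 2L) next
    ps <- list()
    for (i in seq_len(L)) {
      lo <- max(1L, i - window); hi <- min(L, i + window)
      ctx <- setdiff(lo:hi, i)
      ps[[i]] <- cbind(walk[i], walk[ctx])
    }
    out[[w]] <- do.call(rbind, ps)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

skipPairs <- function(walks, scale) {
  out <- lapply(walks, function(walk) {
    L <- length(walk)
    if (L <= scale) return(NULL)
    i <- seq_len(L - scale)
    rbind(cbind(walk[i], walk[i + scale]), cbind(walk[i + scale], walk[i]))
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1L))])
}

#' Random-walk node embeddings for a brain graph
#'
#' `"node2vec"` runs second-order biased walks (return parameter `p`,
#' in-out parameter `q`) and trains one skip-gram embedding over windowed
#' walk contexts.  `"walklets"` runs first-order walks and trains one
#' sub-embedding per skip scale (contexts exactly `k` steps apart),
#' concatenating the scales.  Deterministic under `seed`.
#'
#' @param graph a [BrainGraph-class] (or adjacency matrix).
#' @param method `"node2vec"` or `"walklets"`.
#' @param dimensions embedding width (per scale for walklets).
#' @param walkLength,walksPerNode walk schedule.
#' @param p,q node2vec bias parameters.
#' @param window skip-gram context window (node2vec).
#' @param scales integer skip scales (walklets).
#' @param epochs,learningRate,negatives skip-gram training controls.
#' @param seed integer seed.
#' @return numeric matrix, one embedding row per node.
#' @export
embedNodes <- function(graph, method = c("node2vec", "walklets"),
                       dimensions = 16L, walkLength = 20L, walksPerNode = 50L,
                       p = 1, q = 1, window = 5L, scales = 1:3,
                       epochs = 2L, learningRate = 0.025, negatives = 5L,
                       seed = 1L) {
  method <- match.arg(method)
  if (dimensions <= 0L)
    stop("config error: embedding dimension must be positive", call. = FALSE)
  adj <- if (is(graph, "BrainGraph")) adjacency(graph) else as.matrix(graph)
  n <- nrow(adj)
  if (n == 1L || all(adj == 0)) {
    width <- if (method == "walklets") dimensions * length(scales) else dimensions
    return(matrix(0, n, width))
  }
  set.seed(substreamSeed(seed, paste0("embed-", method)))
  if (method == "node2vec") {
    walks <- randomWalks(adj, walkLength, walksPerNode, p = p, q = q,
                         secondOrder = TRUE)
    trainSkipGram(contextPairs(walks, window), n, dimensions,
                  epochs = epochs, learningRate = learningRate,
                  negatives = negatives)
  } else {
    walks <- randomWalks(adj, walkLength, walksPerNode, secondOrder = FALSE)
    do.call(cbind, lapply(scales, function(k)
      trainSkipGram(skipPairs(walks, k), n, dimensions, epochs = epochs,
                    learningRate = learningRate, negatives = negatives)))
  }
}
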