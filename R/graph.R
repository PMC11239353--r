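# Graph construction: connectivity -> adjacency -> normalized Laplacian ->
# rescaled Chebyshev operator; spectral filtering.

#' Convert a connectivity matrix to a nonnegative adjacency
#'
#' `"abs"` takes absolute correlations; `"positive"` clips negative
#' entries to zero.  The diagonal is zeroed either way.
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param mode `"abs"` (default) or `"positive"`.
#' @return symmetric nonnegative matrix with zero diagonal.
#' @export
toAdjacency <- function(conn, mode = c("abs", "positive")) {
  mode <- match.arg(mode)
  a <- connValues(conn)
  a <- if (mode == "abs") abs(a) else pmax(a, 0)
  diag(a) <- 0
  if (all(a == 0))
    stop("isolated graph: adjacency is identically zero", call. = FALSE)
  (a + base::t(a)) / 2
}

#' Build a BrainGraph from an adjacency matrix
#'
#' Computes the normalized Laplacian \eqn{L = I - D^{-1/2} A D^{-1/2}},
#' its largest eigenvalue by symmetric eigendecomposition (graphs here are
#' small; set `lambdaMaxApprox = TRUE` to use the spectral bound 2
#' instead), and the rescaled operator \eqn{\tilde L = (2/\lambda_{max}) L - I}.
#' Zero-degree nodes get their degree regularized by `epsilon` with a
#' warning rather than failing.
#'
#' @param adjacency symmetric nonnegative matrix, zero diagonal.
#' @param features optional N x F node-feature matrix.
#' @param lambdaMaxApprox logical; use \eqn{\lambda_{max} = 2}.
#' @param epsilon degree regularizer for isolated nodes.
#' @return a [BrainGraph-class].
#' @export
#' @examples
#' a <- matrix(1, 3, 3); diag(a) <- 0
#' g <- buildGraph(a)
#' eigen(laplacian(g))$values  # K3: {1.5, 1.5, 0}
buildGraph <- function(adjacency, features = NULL, lambdaMaxApprox = FALSE,
                       epsilon = 1e-6) {
  if (!isSymmetricMat(adjacency, tol = 1e-9))
    stop("shape error: adjacency must be a symmetric matrix", call. = FALSE)
  a <- (adjacency + base::t(adjacency)) / 2
  diag(a) <- 0
  n <- nrow(a)
  deg <- rowSums(a)
  if (any(deg == 0)) {
    warning("zero-degree node(s); regularizing degree by ", epsilon)
    deg[deg == 0] <- epsilon
  }
  dInv <- 1 / sqrt(deg)
  lap <- diag(n) - dInv * base::t(dInv * a)   # I - D^{-1/2} A D^{-1/2}
  lap <- (lap + base::t(lap)) / 2
  lmax <- if (lambdaMaxApprox) 2 else
    max(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  scaled <- (2 / lmax) * lap - diag(n)
  if (is.null(features)) features <- matrix(numeric(0), n, 0)
  new("BrainGraph", adjacency = a, laplacian = lap,
      scaledLaplacian = scaled, lambdaMax = lmax,
      nodeFeatures = as.matrix(features))
}

#' Chebyshev polynomial basis of the rescaled Laplacian
#'
#' Terms follow the recurrence \eqn{T_0 = I}, \eqn{T_1 = \tilde L},
#' \eqn{T_k = 2 \tilde L T_{k-1} - T_{k-2}}.
#'
#' @param graph a [BrainGraph-class] (or a square matrix taken as
#'   \eqn{\tilde L} directly).
#' @param K polynomial order (>= 1); returns K + 1 terms.
#' @return list of N x N matrices `T0 ... TK`.
#' @export
chebBasis <- function(graph, K) {
  if (!is.numeric(K) || K < 1L)
    stop("config error: Chebyshev order K must be >= 1", call. = FALSE)
  K <- as.integer(K)
  lt <- if (is(graph, "BrainGraph")) scaledLaplacian(graph) else as.matrix(graph)
  n <- nrow(lt)
  terms <- vector("list", K + 1L)
  terms[[1]] <- diag(n)
  terms[[2]] <- lt
  if (K >= 2L) for (k in 3:(K + 1L))
    terms[[k]] <- 2 * lt %*% terms[[k - 1L]] - terms[[k - 2L]]
  names(terms) <- paste0("T", 0:K)
  terms
}

#' Apply a K-order Chebyshev spectral filter to a node signal
#'
#' Computes \eqn{\sum_{k=0}^{K} \theta_k T_k(\tilde L) x}, the polynomial
#' approximation of spectral filtering that avoids an explicit
#' eigendecomposition.
#'
#' @param graph a [BrainGraph-class].
#' @param x numeric node signal of length N (or N x F matrix).
#' @param theta coefficients `theta_0 ... theta_K` (length K + 1).
#' @return filtered signal with the shape of `x`.
#' @export
spectralFilter <- function(graph, x, theta) {
  x <- as.matrix(x)
  n <- nrow(scaledLaplacian(graph))
  if (nrow(x) != n)
    stop("shape error: signal length must equal the node count", call. = FALSE)
  if (length(theta) < 1L)
    stop("shape error: need at least theta_0", call. = FALSE)
  K <- length(theta) - 1L
  if (K == 0L) return(drop(theta[1] * x))
  terms <- chebBasis(graph, K)
  out <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(theta)) out <- out + theta[k] * terms[[k]] %*% x
  drop(out)
}
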