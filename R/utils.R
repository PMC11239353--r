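# Internal helpers shared across modules: seed fan-out, Fisher transform,
# covariance checks.

#' Derive a reproducible sub-stream seed from a master seed and a stage name
#'
#' A single user-facing seed fans out to named sub-streams (cohort, init,
#' shuffle, shap, ...) so pipeline stages can be re-run independently while
#' staying deterministic.  The derived value is always a valid 32-bit integer
#' seed.
#'
#' @param seed integer master seed.
#' @param name character stage name.
#' @return an integer seed.
#' @export
#' @examples
#' substreamSeed(1L, "cohort")
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 31 + cc) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483629 + 1)
}

# Fisher z-transform with clipping so |r| = 1 stays finite.
fisherTransform <- function(r, eps = 1e-7) atanh(pmin(pmax(r, -1 + eps), 1 - eps))

fisherInverse <- function(z) tanh(z)

# Symmetry / PSD checks used by config validation.
isSymmetricMat <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - base::t(m))) <= tol
}

assertPSD <- function(m, label = "covariance", tol = 1e-8) {
  if (!isSymmetricMat(m, tol = 1e-6))
    stop(label, " must be a symmetric matrix", call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol)
    stop(label, " is not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")", call. = FALSE)
  invisible(TRUE)
}

# Uniform-block correlation matrix builder used for generator defaults:
# within-network blocks get `within`, between-network block gets `between`.
blockCorrelation <- function(networks, within, between = 0) {
  n <- length(networks)
  m <- matrix(between, n, n)
  for (net in unique(networks)) {
    idx <- which(networks == net)
    m[idx, idx] <- within[[net]]
  }
  diag(m) <- 1
  m
}

# Column z-scoring; guards zero variance with an informative error.
zscoreColumns <- function(x, roiNames = colnames(x), context = "window") {
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    bad <- if (is.null(roiNames)) which(sds == 0) else roiNames[sds == 0]
    stop("degenerate signal: zero variance in ", context, " for ROI(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  scale(x)
}

vcapply <- function(x, f, ...) vapply(x, f, character(1L), ...)
vnapply <- function(x, f, ...) vapply(x, f, numeric(1L), ...)
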