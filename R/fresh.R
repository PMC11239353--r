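# Statistical time-series features per node with hypothesis-test-based
# selection (scalable-hypothesis-test style): every candidate feature is
# tested for relevance to the class label, and the Benjamini-Yekutieli
# procedure decides which features to keep.

#' Per-series statistical feature catalog
#'
#' A fixed, documented 10-statistic catalog: mean, variance, skewness,
#' kurtosis, autocorrelation at lags 1-3, energy (sum of squares),
#' absolute sum of changes, and the linear-trend slope.
#'
#' @param x numeric vector (one node's windowed time-series).
#' @return named numeric vector of length 10.
#' @export
#' @examples
#' featureCatalog(sin(1:20))
featureCatalog <- function(x) {
  n <- length(x)
  mu <- mean(x)
  s <- sd(x)
  ctr <- x - mu
  acfs <- if (s == 0) c(0, 0, 0) else
    drop(acf(x, lag.max = 3, plot = FALSE, demean = TRUE)$acf)[2:4]
  slope <- if (n < 2L) 0 else unname(coef(lm(x ~ seq_len(n)))[2])
  c(mean = mu,
    variance = if (n < 2L) 0 else var(x),
    skewness = if (s == 0) 0 else mean(ctr^3) / s^3,
    kurtosis = if (s == 0) 0 else mean(ctr^4) / s^4 - 3,
    acf_lag1 = acfs[1], acf_lag2 = acfs[2], acf_lag3 = acfs[3],
    energy = sum(x^2),
    abs_sum_changes = sum(abs(diff(x))),
    trend_slope = slope)
}

#' Relevance-tested node feature selection
#'
#' Extracts the [featureCatalog()] statistics for every (sample, node)
#' series, tests each node-feature column for association with the binary
#' class label by a Mann-Whitney U test, adjusts the p-values with the
#' Benjamini-Yekutieli procedure across all node x feature columns, and
#' keeps the feature statistics that survive at `fdrLevel` for at least
#' one node (so every node retains the same feature set).
#'
#' @param series numeric array `samples x time x nodes`, or a list of
#'   `time x nodes` matrices.
#' @param labels class label per sample (exactly 2 classes required).
#' @param fdrLevel Benjamini-Yekutieli level (default 0.05).
#' @return list with `features` (array `samples x nodes x kept`),
#'   `selected` (kept statistic names), `pvalues` (adjusted p-value matrix
#'   statistic x node) and `empty` flag (TRUE when nothing survived).
#' @export
freshSelect <- function(series, labels, fdrLevel = 0.05) {
  if (is.list(series))
    series <- aperm(simplify2array(series), c(3L, 1L, 2L))
  stopifnot(length(dim(series)) == 3L)
  nS <- dim(series)[1]; nNode <- dim(series)[3]
  labels <- as.character(labels)
  if (length(labels) != nS)
    stop("labels must match the number of samples", call. = FALSE)
  if (nS < 8L) stop("need >= 8 samples for relevance testing", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) != 2L)
    stop("relevance testing requires exactly 2 classes, got ",
         length(classes), call. = FALSE)
  statNames <- names(featureCatalog(series[1, , 1]))
  feat <- array(NA_real_, c(nS, nNode, length(statNames)),
                dimnames = list(NULL, NULL, statNames))
  for (s in seq_len(nS)) for (v in seq_len(nNode))
    feat[s, v, ] <- featureCatalog(series[s, , v])
  g1 <- labels == classes[1]
  praw <- matrix(NA_real_, length(statNames), nNode,
                 dimnames = list(statNames, NULL))
  for (f in seq_along(statNames)) for (v in seq_len(nNode)) {
    x1 <- feat[g1, v, f]; x2 <- feat[!g1, v, f]
    praw[f, v] <- if (sd(c(x1, x2)) == 0) 1 else
      suppressWarnings(wilcox.test(x1, x2, exact = FALSE)$p.value)
  }
  padj <- matrix(p.adjust(praw, method = "BY"), nrow(praw), ncol(praw),
                 dimnames = dimnames(praw))
  keep <- statNames[apply(padj < fdrLevel, 1L, any)]
  if (!length(keep)) {
    warning("no feature survived Benjamini-Yekutieli selection at level ",
            fdrLevel)
    return(list(features = feat[, , 0, drop = FALSE], selected = character(),
                pvalues = padj, empty = TRUE))
  }
  list(features = feat[, , keep, drop = FALSE], selected = keep,
       pvalues = padj, empty = FALSE)
}
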