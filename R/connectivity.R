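# FC / ISFC computation and edge-level statistics.

# Extract one window's rows, z-scored per column.
windowBlock <- function(ts, window) {
  stopifnot(is(ts, "BoldTimeSeries"))
  x <- ts@data[window$start:window$end, , drop = FALSE]
  if (nrow(x) < 3L) stop("window must span at least 3 time points",
                         call. = FALSE)
  zscoreColumns(x, roiNames = roiNames(ts),
                context = paste0("window ", window$label))
}

#' Within-subject functional connectivity for one event window
#'
#' Pearson correlation between the ROI time-series over the window
#' (columns are z-scored first; Pearson is scale-invariant, so this only
#' stabilizes downstream averaging).
#'
#' @param ts a [BoldTimeSeries-class].
#' @param window one row of the window schedule (list/data.frame with
#'   `label`, `start`, `end`).
#' @return a [ConnectivityMatrix-class] of kind `"FC"`.
#' @export
#' @examples
#' cfg <- cohortConfig(nSubjects = 2,
#'                     groupSizes = c(pass = 2, inconsistent = 0, fail = 0),
#'                     ageGroups = c(child = 2, adult = 0), seed = 3)
#' coh <- generateCohort(cfg)
#' fc <- computeFC(coh[[1]], windowSchedule(coh)[1, ])
computeFC <- function(ts, window) {
  x <- windowBlock(ts, window)
  v <- cor(x)
  v <- (v + base::t(v)) / 2
  diag(v) <- 1
  new("ConnectivityMatrix", values = v, kind = "FC",
      subjectId = ts@subjectId, windowLabel = as.character(window$label),
      roiNames = roiNames(ts))
}

#' Leave-one-out inter-subject functional correlation for one window
#'
#' For subject s, entry (i, j) is the correlation of subject s's ROI i
#' signal with the average over all OTHER subjects of ROI j, computed over
#' the window, then symmetrized as \eqn{(M + M^T)/2}.  ISFC isolates
#' stimulus-locked coupling: components not shared across subjects
#' (intrinsic activity, noise) average out of the leave-one-out mean.
#'
#' @param tsList list of [BoldTimeSeries-class] (>= 2 subjects, identical
#'   ROI sets and window schedule).
#' @param window one row of the window schedule.
#' @return list of [ConnectivityMatrix-class] of kind `"ISFC"`, one per
#'   subject, in input order.
#' @export
computeISFC <- function(tsList, window) {
  if (length(tsList) < 2L)
    stop("ISFC requires >=2 subjects", call. = FALSE)
  rois <- roiNames(tsList[[1]])
  blocks <- lapply(tsList, function(ts) {
    if (!identical(roiNames(ts), rois))
      stop("shape error: mismatched ROI sets across subjects", call. = FALSE)
    windowBlock(ts, window)
  })
  total <- Reduce(`+`, blocks)
  nSub <- length(blocks)
  lapply(seq_len(nSub), function(s) {
    others <- (total - blocks[[s]]) / (nSub - 1)
    m <- cor(blocks[[s]], others)
    v <- (m + base::t(m)) / 2
    v[v > 1] <- 1; v[v < -1] <- -1
    new("ConnectivityMatrix", values = v, kind = "ISFC",
        subjectId = tsList[[s]]@subjectId,
        windowLabel = as.character(window$label), roiNames = rois)
  })
}

#' Entrywise average of connectivity matrices
#'
#' Optionally averages on the Fisher z scale (mean of `atanh`, then
#' `tanh`), clipping |r| at 1 - 1e-7 before the transform so unit
#' diagonals stay finite.
#'
#' @param matrices list of [ConnectivityMatrix-class] with a common shape.
#' @param fisherZ logical; average on the z scale.
#' @return a [ConnectivityMatrix-class] (kind of the first input, subject
#'   `"group"` unless all inputs share one subject).
#' @export
averageMatrices <- function(matrices, fisherZ = TRUE) {
  if (!length(matrices)) stop("cannot average an empty list", call. = FALSE)
  vals <- lapply(matrices, connValues)
  dims <- vapply(vals, nrow, integer(1L))
  if (length(unique(dims)) != 1L)
    stop("shape error: matrices differ in dimension", call. = FALSE)
  avg <- if (fisherZ) {
    fisherInverse(Reduce(`+`, lapply(vals, fisherTransform)) / length(vals))
  } else {
    Reduce(`+`, vals) / length(vals)
  }
  k <- connKind(matrices[[1]])
  if (k == "FC") diag(avg) <- 1
  ids <- unique(vcapply(matrices, function(m) m@subjectId))
  new("ConnectivityMatrix", values = avg, kind = k,
      subjectId = if (length(ids) == 1L) ids else "group",
      windowLabel = "average", roiNames = roiNames(matrices[[1]]))
}

#' Edge-wise one-sample t-tests with FDR correction
#'
#' For each unique edge, a one-sample t-test of the Fisher-z transformed
#' values against zero across matrices, with Benjamini-Hochberg adjustment
#' over the N(N-1)/2 edges.  An edge survives when its adjusted p-value
#' falls below `alpha`.  Zero-variance edges (every subject identical) get
#' a degenerate-t flag; they survive when their common value is nonzero.
#'
#' @param matrices list of >= 3 [ConnectivityMatrix-class].
#' @param alpha significance level for the FDR decision (default 0.01).
#' @param band half-width of the "moderate" strength band around 0.5
#'   passed to [classifyEdgeStrength()].
#' @return data.frame with one row per edge: `roi_i`, `roi_j`, `mean_r`,
#'   `t`, `p`, `q`, `survives`, `degenerate`, `strength`.
#' @export
edgeTTests <- function(matrices, alpha = 0.01, band = 0.05) {
  if (length(matrices) < 3L)
    stop("insufficient sample: edge t-tests need >= 3 matrices",
         call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  rois <- roiNames(matrices[[1]])
  n <- length(rois)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  zvals <- vapply(matrices, function(m) fisherTransform(connValues(m))[idx],
                  numeric(nrow(idx)))
  res <- data.frame(roi_i = rois[idx[, 1]], roi_j = rois[idx[, 2]],
                    stringsAsFactors = FALSE)
  stats <- apply(zvals, 1, function(z) {
    if (sd(z) == 0) {
      c(t = if (mean(z) == 0) 0 else Inf * sign(mean(z)),
        p = if (mean(z) == 0) 1 else 0, degenerate = 1)
    } else {
      ht <- t.test(z, mu = 0)
      c(t = unname(ht$statistic), p = ht$p.value, degenerate = 0)
    }
  })
  res$mean_r <- fisherInverse(rowMeans(zvals))
  res$t <- stats["t", ]
  res$p <- stats["p", ]
  res$q <- p.adjust(res$p, method = "BH")
  res$survives <- res$q < alpha
  res$degenerate <- stats["degenerate", ] == 1
  res$strength <- vcapply(res$mean_r, classifyEdgeStrength, band = band)
  attr(res, "alpha") <- alpha
  res
}

#' Classify edge strength relative to the 0.5 benchmark
#'
#' Correlations above 0.5 indicate strong connectivity, values near 0.5
#' moderate connectivity, and values below weak connectivity.  "Near" is a
#' configurable band of half-width `band` around 0.5.
#'
#' @param value correlation in \[-1, 1\].
#' @param band half-width of the moderate band (> 0, default 0.05).
#' @return `"strong"`, `"moderate"` or `"weak"`.
#' @export
#' @examples
#' classifyEdgeStrength(0.9)   # strong
#' classifyEdgeStrength(0.5)   # moderate
#' classifyEdgeStrength(-0.2)  # weak
classifyEdgeStrength <- function(value, band = 0.05) {
  stopifnot(length(value) == 1L, value >= -1 - 1e-9, value <= 1 + 1e-9,
            band > 0)
  if (abs(value - 0.5) <= band) "moderate"
  else if (value > 0.5 + band) "strong"
  else "weak"
}
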