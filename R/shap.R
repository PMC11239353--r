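# Shapley-value attribution: exact subset enumeration for small feature
# sets, Monte-Carlo permutation sampling for larger ones, and ROI-level
# aggregation of attributions into "brain fingerprints".

#' Exact Shapley values by subset enumeration
#'
#' Computes \eqn{\phi_i = \sum_{S \not\ni i} \frac{|S|!(n-|S|-1)!}{n!}
#' [val(S \cup i) - val(S)]} over all \eqn{2^n} subsets.  The value
#' function receives a logical inclusion vector; how "absent" features are
#' handled (e.g. background-mean imputation, see [maskedValueFn()]) is the
#' caller's choice.  Satisfies efficiency, symmetry and the dummy axiom
#' exactly.
#'
#' @param valueFn function(logical vector of length `nFeatures`) -> scalar.
#' @param nFeatures number of features (<= 16; use [shapSample()] beyond).
#' @param featureNames optional names for the result.
#' @return a [ShapAttribution-class].
#' @export
#' @examples
#' # additive game: phi_i equals the feature's own contribution
#' shapValues(shapExact(function(s) sum(which(s)), 3))
shapExact <- function(valueFn, nFeatures, featureNames = NULL) {
  if (nFeatures > 16L)
    stop("exact enumeration is limited to 16 features; use shapSample()",
         call. = FALSE)
  n <- as.integer(nFeatures)
  nSub <- 2L^n
  vals <- numeric(nSub)
  sizes <- integer(nSub)
  bits <- function(m) as.logical(bitwAnd(m, bitwShiftL(1L, 0:(n - 1L))))
  for (m in 0:(nSub - 1L)) {
    s <- bits(m)
    vals[m + 1L] <- valueFn(s)
    sizes[m + 1L] <- sum(s)
  }
  wt <- factorial(0:(n - 1L)) * factorial(n - 1L - 0:(n - 1L)) / factorial(n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (m in 0:(nSub - 1L)) {
      if (bitwAnd(m, bit) == 0L) {
        phi[i] <- phi[i] + wt[sizes[m + 1L] + 1L] *
          (vals[bitwOr(m, bit) + 1L] - vals[m + 1L])
      }
    }
  }
  if (is.null(featureNames)) featureNames <- paste0("f", seq_len(n))
  new("ShapAttribution", phi = setNames(phi, featureNames),
      se = numeric(n), baseline = vals[1L], fullValue = vals[nSub],
      method = "exact")
}

#' Monte-Carlo Shapley values by permutation sampling
#'
#' Averages marginal contributions over random feature orderings;
#' per-feature standard errors come from the permutation-level spread.
#' Deterministic under `seed`.
#'
#' @inheritParams shapExact
#' @param nPermutations number of sampled orderings (>= 50).
#' @param seed integer seed.
#' @return a [ShapAttribution-class] with standard errors.
#' @export
shapSample <- function(valueFn, nFeatures, nPermutations = 200L, seed = 1L,
                       featureNames = NULL) {
  if (nPermutations < 50L)
    stop("need at least 50 permutations", call. = FALSE)
  n <- as.integer(nFeatures)
  set.seed(substreamSeed(seed, "shap"))
  contrib <- matrix(NA_real_, nPermutations, n)
  baseline <- valueFn(rep(FALSE, n))
  fullValue <- valueFn(rep(TRUE, n))
  for (p in seq_len(nPermutations)) {
    ord <- sample.int(n)
    s <- rep(FALSE, n)
    prev <- baseline
    for (i in ord) {
      s[i] <- TRUE
      cur <- valueFn(s)
      contrib[p, i] <- cur - prev
      prev <- cur
    }
  }
  phi <- colMeans(contrib)
  se <- apply(contrib, 2L, sd) / sqrt(nPermutations)
  if (is.null(featureNames)) featureNames <- paste0("f", seq_len(n))
  new("ShapAttribution", phi = setNames(phi, featureNames),
      se = se, baseline = baseline, fullValue = fullValue,
      method = "sampled")
}

#' Background-imputing value function for model explanations
#'
#' Wraps a prediction function of a full feature vector into a subset
#' value function: features absent from the subset are replaced by the
#' background (training-set mean) values, the single-reference convention.
#'
#' @param predictFn function(numeric feature vector) -> scalar model output.
#' @param x the feature vector being explained.
#' @param background reference values for absent features (same length).
#' @return function(logical subset) -> scalar, usable with [shapExact()] /
#'   [shapSample()].
#' @export
maskedValueFn <- function(predictFn, x, background) {
  stopifnot(length(x) == length(background))
  function(s) {
    v <- background
    v[s] <- x[s]
    predictFn(v)
  }
}

#' Rank ROIs by median absolute attribution
#'
#' Aggregates per-sample attributions to ROI level: ROI-level features map
#' directly; edge-level features (named `"A--B"`) contribute to both
#' endpoint ROIs.  Scores are the median of |phi| across samples and
#' contributing features, ranked descending (ties keep ROI-table order).
#'
#' @param attributions list of [ShapAttribution-class] (one per explained
#'   sample) with shared feature names.
#' @param roiNames ROI labels defining the output order.
#' @param networks optional per-ROI network tags enabling top-k-per-network
#'   extraction.
#' @param topPerNetwork how many leading ROIs per network to flag as
#'   dominant (default 3, mirroring the 3 ToM + 3 Pain convention).
#' @return data.frame ranked by score with columns `roi`, `network`,
#'   `score`, `rank`, `dominant`.
#' @export
rankRois <- function(attributions, roiNames, networks = NULL,
                     topPerNetwork = 3L) {
  if (!length(attributions)) stop("empty attribution list", call. = FALSE)
  if (is(attributions, "ShapAttribution")) attributions <- list(attributions)
  featNames <- names(shapValues(attributions[[1]]))
  perRoi <- lapply(roiNames, function(r) {
    hit <- featNames == r |
      vapply(strsplit(featNames, "--", fixed = TRUE),
             function(p) r %in% p, logical(1L))
    unlist(lapply(attributions, function(a) abs(shapValues(a))[hit]))
  })
  score <- vnapply(perRoi, function(v) if (length(v)) median(v) else 0)
  ord <- order(-score)          # stable: ties keep ROI-table order
  out <- data.frame(roi = roiNames[ord],
                    network = if (is.null(networks)) NA_character_
                              else networks[ord],
                    score = score[ord])
  out$rank <- seq_len(nrow(out))
  out$dominant <- FALSE
  if (!is.null(networks)) {
    for (net in unique(out$network)) {
      idx <- which(out$network == net)
      out$dominant[head(idx, topPerNetwork)] <- TRUE
    }
  } else {
    out$dominant[seq_len(min(2L * topPerNetwork, nrow(out)))] <- TRUE
  }
  rownames(out) <- NULL
  out
}
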