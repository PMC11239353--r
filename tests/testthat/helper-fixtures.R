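# Shared fixtures: small cohorts, tiny graphs, hand-built time-series.

`%||%` <- function(a, b) if (is.null(a)) b else a

smallCohortConfig <- function(n = 12L, seed = 1L, coupling = c(pass = 0.8,
                              inconsistent = 0.5, fail = 0.2), ...) {
  third <- n %/% 3L
  cohortConfig(nSubjects = n,
               groupSizes = c(pass = n - 2L * third, inconsistent = third,
                              fail = third),
               ageGroups = c(child = n, adult = 0L),
               groupCoupling = coupling, seed = seed, ...)
}

singleGroupConfig <- function(n = 4L, seed = 1L, coupling = 0, ...) {
  cohortConfig(nSubjects = n,
               groupSizes = c(pass = n, inconsistent = 0L, fail = 0L),
               ageGroups = c(child = n, adult = 0L),
               groupCoupling = c(pass = coupling, inconsistent = 0.5,
                                 fail = 0.2),
               seed = seed, ...)
}

# BoldTimeSeries from an explicit matrix (windows default to one window
# covering the whole series).
makeSeries <- function(data, id = "s1", windows = NULL) {
  n <- ncol(data)
  rs <- newRoiSet(paste0("R", seq_len(n)),
                  rep(c("ToM", "Pain"), length.out = n))
  colnames(data) <- rs@names
  if (is.null(windows))
    windows <- data.frame(label = "W1", state = "ToM", start = 1L,
                          end = nrow(data), description = "")
  new("BoldTimeSeries", subjectId = id, data = data, windows = windows,
      roiSet = rs, trSeconds = 2)
}

randomGraph <- function(n, seed = NULL, features = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- abs(matrix(rnorm(n * n), n))
  a <- (a + t(a)) / 2
  diag(a) <- 0
  buildGraph(a, features = features)
}

symCorr <- function(n, scale = 0.3) {
  v <- matrix(rnorm(n * n, sd = scale), n, n)
  v <- (v + t(v)) / 2
  v <- pmin(pmax(v, -0.99), 0.99)
  diag(v) <- 1
  v
}

makeConn <- function(v, kind = "FC", id = "s1", window = "W1") {
  new("ConnectivityMatrix", values = v, kind = kind, subjectId = id,
      windowLabel = window, roiNames = paste0("R", seq_len(nrow(v))))
}
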