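# Validation protocols: repeated shuffled 80:20 splits, stratified 5-fold
# cross-validation, leave-one-out, and the metric suite.  All schemes
# split at the SUBJECT level so the windows of one subject never straddle
# the train/test boundary.

#' Build subject-level train/test splits
#'
#' `repeated_8020`: 10 (by default) independent shuffles; the first
#' \eqn{\lfloor 0.8 n \rfloor} subjects train, the rest test, stratified by
#' class when `labels` are given.  `kfold5`: five disjoint folds covering
#' all subjects.  `loo`: one split per subject.
#'
#' @param n number of subjects (or a vector of subject ids).
#' @param scheme `"repeated_8020"`, `"kfold5"` or `"loo"`.
#' @param seed integer seed.
#' @param labels optional per-subject class labels for stratification.
#' @param nRepeats shuffles for `repeated_8020`.
#' @return list of splits, each `list(train, test, repeat_index)` of
#'   disjoint index vectors covering `1:n`.
#' @export
#' @examples
#' sp <- makeSplits(155, "repeated_8020", seed = 1)
#' lengths(sp[[1]][c("train", "test")])  # 124 / 31
makeSplits <- function(n, scheme = c("repeated_8020", "kfold5", "loo"),
                       seed = 1L, labels = NULL, nRepeats = 10L) {
  scheme <- match.arg(scheme)
  if (length(n) > 1L) n <- length(n)
  n <- as.integer(n)
  if (scheme == "kfold5" && n < 5L)
    stop("five-fold cross-validation needs >= 5 subjects", call. = FALSE)
  if (n < 2L) stop("need >= 2 subjects", call. = FALSE)
  set.seed(substreamSeed(seed, paste0("splits-", scheme)))
  if (scheme == "repeated_8020") {
    nTrain <- floor(0.8 * n)
    lapply(seq_len(nRepeats), function(r) {
      if (is.null(labels)) {
        ord <- sample.int(n)
        train <- ord[seq_len(nTrain)]
      } else {
        # proportional allocation per class, topped up from the shuffled
        # remainder so |train| is exactly floor(0.8 n)
        pools <- lapply(split(seq_len(n), labels), sample)
        train <- unlist(lapply(pools, function(p)
          p[seq_len(floor(0.8 * length(p)))]), use.names = FALSE)
        rest <- sample(setdiff(seq_len(n), train))
        if (length(train) < nTrain)
          train <- c(train, rest[seq_len(nTrain - length(train))])
      }
      list(train = sort(train), test = sort(setdiff(seq_len(n), train)),
           repeat_index = r)
    })
  } else if (scheme == "kfold5") {
    # cycling fold ids over per-class shuffles keeps folds stratified
    ord <- if (is.null(labels)) sample.int(n) else
      unlist(lapply(split(seq_len(n), labels), sample), use.names = FALSE)
    folds <- split(ord, rep_len(1:5, length(ord)))
    lapply(1:5, function(k)
      list(train = sort(unlist(folds[-k], use.names = FALSE)),
           test = sort(folds[[k]]), repeat_index = k))
  } else {
    lapply(seq_len(n), function(i)
      list(train = setdiff(seq_len(n), i), test = i, repeat_index = i))
  }
}

#' Classification metrics, confusion matrix and curves
#'
#' Per-class and macro precision / recall / F1, overall accuracy, the
#' confusion matrix, and (when scores are supplied) ROC and
#' precision-recall curve points - one-vs-rest per class for more than two
#' classes.
#'
#' @param predictions predicted labels.
#' @param truths true labels (same length).
#' @param scores optional score matrix (columns = classes) for curves.
#' @param labels label set; defaults to the union of values seen.
#' @return list with `accuracy`, `confusion`, `perClass` (data.frame),
#'   `macro` (precision/recall/f1), and optionally `roc` / `pr`
#'   (long-format data.frames of curve points with per-class AUC).
#' @export
computeMetrics <- function(predictions, truths, scores = NULL,
                           labels = NULL) {
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length", call. = FALSE)
  if (is.null(labels))
    labels <- sort(unique(c(as.character(predictions), as.character(truths))))
  predictions <- factor(predictions, levels = labels)
  truths <- factor(truths, levels = labels)
  conf <- table(truth = truths, prediction = predictions)
  acc <- sum(diag(conf)) / sum(conf)
  perClass <- do.call(rbind, lapply(labels, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               support = sum(conf[cl, ]))
  }))
  out <- list(accuracy = acc, confusion = conf, perClass = perClass,
              macro = c(precision = mean(perClass$precision),
                        recall = mean(perClass$recall),
                        f1 = mean(perClass$f1)))
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (is.null(colnames(scores))) colnames(scores) <- labels
    curves <- lapply(labels, function(cl) {
      truthBin <- as.integer(truths == cl)
      if (length(unique(truthBin)) < 2L) return(NULL)
      r <- pROC::roc(truthBin, scores[, cl], quiet = TRUE,
                     direction = "<", levels = c(0, 1))
      rocDf <- data.frame(class = cl, fpr = 1 - r$specificities,
                          tpr = r$sensitivities,
                          auc = as.numeric(r$auc))
      ord <- order(-scores[, cl])
      tp <- cumsum(truthBin[ord])
      prec <- tp / seq_along(tp)
      rec <- tp / sum(truthBin)
      prDf <- data.frame(class = cl, recall = rec, precision = prec)
      list(roc = rocDf, pr = prDf)
    })
    curves <- curves[!vapply(curves, is.null, logical(1L))]
    if (length(curves)) {
      out$roc <- do.call(rbind, lapply(curves, `[[`, "roc"))
      out$pr <- do.call(rbind, lapply(curves, `[[`, "pr"))
    }
  }
  out
}

# Guard used by experiment runners: train/test subject sets disjoint.
assertNoLeakage <- function(split) {
  if (length(intersect(split$train, split$test)))
    stop("subject leakage: train and test sets overlap", call. = FALSE)
  invisible(TRUE)
}
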