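# End-to-end experiment orchestration: cohort -> connectivity -> graphs ->
# model -> metrics (-> attribution).

#' Per-subject, per-window connectivity for a whole cohort
#'
#' FC is computed within subject; ISFC is computed per window across the
#' full cohort (leave-one-out against the group mean), matching how
#' stimulus-locked coupling is estimated for naturalistic designs.
#'
#' @param cohort a [Cohort-class].
#' @param kind `"FC"` or `"ISFC"`.
#' @return list over subjects, each a list over windows of
#'   [ConnectivityMatrix-class].
#' @export
cohortConnectivity <- function(cohort, kind = c("FC", "ISFC")) {
  kind <- match.arg(kind)
  w <- windowSchedule(cohort)
  if (kind == "FC") {
    lapply(cohort@subjects, function(ts)
      lapply(seq_len(nrow(w)), function(i) computeFC(ts, w[i, ])))
  } else {
    perWindow <- lapply(seq_len(nrow(w)), function(i)
      computeISFC(cohort@subjects, w[i, ]))
    lapply(seq_along(cohort@subjects), function(s)
      lapply(perWindow, `[[`, s))
  }
}

#' Restrict a connectivity matrix to a subset of ROIs
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param rois ROI names to keep (in the requested order).
#' @return a [ConnectivityMatrix-class] over `rois`.
#' @export
subsetConnectivity <- function(conn, rois) {
  keep <- match(rois, roiNames(conn))
  if (anyNA(keep))
    stop("config error: unknown ROI(s): ",
         paste(rois[is.na(keep)], collapse = ", "), call. = FALSE)
  new("ConnectivityMatrix", values = connValues(conn)[keep, keep],
      kind = connKind(conn), subjectId = conn@subjectId,
      windowLabel = conn@windowLabel, roiNames = rois)
}

#' Build a BrainGraph from one connectivity matrix
#'
#' The adjacency comes from [toAdjacency()]; node features are, by
#' default, the rows of the connectivity matrix (each node's connectivity
#' profile).  `featureMode = "embedding"` appends random-walk embeddings;
#' an explicit `features` matrix overrides both.
#'
#' @param conn a [ConnectivityMatrix-class].
#' @param adjacencyMode passed to [toAdjacency()].
#' @param featureMode `"rows"`, `"embedding"`, `"rows+embedding"`.
#' @param features optional explicit node-feature matrix.
#' @param embedArgs list of arguments for [embedNodes()].
#' @return a [BrainGraph-class].
#' @export
graphFromConnectivity <- function(conn, adjacencyMode = "abs",
                                  featureMode = c("rows", "embedding",
                                                  "rows+embedding"),
                                  features = NULL, embedArgs = list()) {
  featureMode <- match.arg(featureMode)
  adj <- toAdjacency(conn, adjacencyMode)
  g <- buildGraph(adj)
  if (is.null(features)) {
    rows <- connValues(conn)
    features <- switch(featureMode,
      rows = rows,
      embedding = do.call(embedNodes, c(list(g), embedArgs)),
      `rows+embedding` = cbind(rows, do.call(embedNodes, c(list(g),
                                                           embedArgs))))
  }
  g@nodeFeatures <- as.matrix(features)
  g
}

#' Flat state-decoding dataset: one graph per subject x window
#'
#' @param cohort a [Cohort-class].
#' @param kind `"FC"` or `"ISFC"`.
#' @param rois optional ROI subset (names).
#' @param adjacencyMode,featureMode graph construction choices (see
#'   [graphFromConnectivity()]).
#' @return list with `graphs` (list of [BrainGraph-class]), `states`
#'   (factor of window states) and `subject` (subject index per graph,
#'   for subject-level splitting).
#' @export
stateDataset <- function(cohort, kind = "ISFC", rois = NULL,
                         adjacencyMode = "abs", featureMode = "rows") {
  conn <- cohortConnectivity(cohort, kind)
  w <- windowSchedule(cohort)
  if (is.null(rois)) rois <- roiNames(cohort)
  graphs <- list(); states <- character(); subj <- integer()
  for (s in seq_along(conn)) {
    for (i in seq_along(conn[[s]])) {
      cm <- conn[[s]][[i]]
      if (!identical(rois, roiNames(cm))) cm <- subsetConnectivity(cm, rois)
      graphs[[length(graphs) + 1L]] <-
        graphFromConnectivity(cm, adjacencyMode, featureMode)
      states <- c(states, w$state[i])
      subj <- c(subj, s)
    }
  }
  list(graphs = graphs, states = factor(states), subject = subj)
}

#' Per-subject mean connectivity across all windows
#'
#' Fisher-z average of the per-window matrices, the per-subject input to
#' the performance-prediction stage.
#'
#' @inheritParams cohortConnectivity
#' @param rois optional ROI subset.
#' @return list of [ConnectivityMatrix-class], one per subject.
#' @export
subjectMeanConnectivity <- function(cohort, kind = c("FC", "ISFC"),
                                    rois = NULL) {
  kind <- match.arg(kind)
  conn <- cohortConnectivity(cohort, kind)
  lapply(conn, function(ms) {
    avg <- averageMatrices(ms, fisherZ = TRUE)
    if (!is.null(rois) && !identical(rois, roiNames(avg)))
      avg <- subsetConnectivity(avg, rois)
    avg
  })
}

resolveRoiSubset <- function(cohort, roiSubset) {
  all <- roiNames(cohort)
  nets <- roiNetwork(cohort@roiSet)
  if (is.null(roiSubset) || identical(roiSubset, "all")) all
  else if (identical(roiSubset, "tom6")) all[nets == "ToM"]
  else roiSubset
}

#' Experiment configuration
#'
#' @param cohort a [cohortConfig()] describing the synthetic cohort (or an
#'   existing [Cohort-class] to reuse).
#' @param featureKind `"ISFC"` (default) or `"FC"`.
#' @param model `"stgcnn"` (state decoding) or `"cvae"` (performance
#'   prediction).
#' @param roiSubset `"all"`, `"tom6"`, or a character vector of ROI names
#'   (e.g. the 8 dominant regions from an attribution run).
#' @param scheme split scheme for [makeSplits()].
#' @param nRepeats repeats for the repeated 80:20 scheme.
#' @param decoder a [decoderConfig()].
#' @param vae a [vaeConfig()] (its `nRoi` is overridden by the subset size).
#' @param includeAdults logical; adults are excluded from the
#'   performance-prediction dataset by default (they carry no behavioral
#'   score).
#' @param adjacencyMode,featureMode graph construction choices.
#' @param seed master seed for splits and training.
#' @return configuration list of class `"ExperimentConfig"`.
#' @export
experimentConfig <- function(cohort = cohortConfig(),
                             featureKind = c("ISFC", "FC"),
                             model = c("stgcnn", "cvae"),
                             roiSubset = "all",
                             scheme = "repeated_8020", nRepeats = 10L,
                             decoder = decoderConfig(),
                             vae = vaeConfig(),
                             includeAdults = FALSE,
                             adjacencyMode = "abs", featureMode = "rows",
                             seed = 1L) {
  structure(list(cohort = cohort, featureKind = match.arg(featureKind),
                 model = match.arg(model), roiSubset = roiSubset,
                 scheme = scheme, nRepeats = as.integer(nRepeats),
                 decoder = decoder, vae = vae,
                 includeAdults = includeAdults,
                 adjacencyMode = adjacencyMode, featureMode = featureMode,
                 seed = as.integer(seed)),
            class = "ExperimentConfig")
}

#' Run a full decode / predict experiment
#'
#' Generates (or reuses) the cohort, computes the requested connectivity
#' features, builds graphs, trains the requested model on each
#' subject-level split and evaluates it.  Subject leakage is asserted on
#' every split.
#'
#' @param config an [experimentConfig()].
#' @return list with `perRepeat` (data.frame of per-split accuracy and
#'   macro F1), `meanAccuracy`, `sdAccuracy`, `metrics` (full metric list
#'   of the last split), `config`, and for `"cvae"` the fitted latent
#'   classifier of the last split.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "ExperimentConfig"))
  cohort <- if (is(config$cohort, "Cohort")) config$cohort
            else generateCohort(config$cohort)
  rois <- resolveRoiSubset(cohort, config$roiSubset)
  meta <- cohortMeta(cohort)

  if (config$model == "stgcnn") {
    ds <- stateDataset(cohort, config$featureKind, rois,
                       config$adjacencyMode, config$featureMode)
    splits <- makeSplits(length(cohort), config$scheme, seed = config$seed,
                         nRepeats = config$nRepeats)
    perRepeat <- data.frame()
    lastMetrics <- NULL
    for (sp in splits) {
      assertNoLeakage(sp)
      trainMask <- ds$subject %in% sp$train
      dcfg <- config$decoder
      dcfg$seed <- substreamSeed(config$seed,
                                 paste0("rep", sp$repeat_index))
      model <- suppressWarnings(
        trainDecoder(ds$graphs[trainMask], ds$states[trainMask], dcfg))
      pred <- predictState(model, ds$graphs[!trainMask])
      m <- computeMetrics(pred$labels, ds$states[!trainMask],
                          scores = pred$probs)
      perRepeat <- rbind(perRepeat, data.frame(
        repeat_index = sp$repeat_index, accuracy = m$accuracy,
        macro_f1 = unname(m$macro["f1"])))
      lastMetrics <- m
    }
  } else {
    keep <- if (config$includeAdults) seq_len(nrow(meta))
            else which(meta$age_group != "adult")
    conns <- subjectMeanConnectivity(cohort, config$featureKind, rois)[keep]
    groups <- factor(meta$group[keep],
                     levels = c("pass", "inconsistent", "fail"))
    splits <- makeSplits(length(keep), config$scheme, seed = config$seed,
                         labels = groups, nRepeats = config$nRepeats)
    vcfg <- config$vae
    vcfg$nRoi <- length(rois)
    perRepeat <- data.frame()
    lastMetrics <- NULL
    lastClassifier <- NULL
    for (sp in splits) {
      assertNoLeakage(sp)
      vcfg$seed <- substreamSeed(config$seed,
                                 paste0("vae-rep", sp$repeat_index))
      vae <- suppressWarnings(
        trainVae(conns[sp$train], structure(vcfg, class = "VaeConfig")))
      zTrain <- vaeEncode(vae, conns[sp$train])$mu
      clf <- trainGroupClassifier(zTrain, groups[sp$train],
                                  batchSize = vcfg$batchPredict,
                                  seed = vcfg$seed)
      zTest <- vaeEncode(vae, conns[sp$test])$mu
      pred <- predictGroup(clf, zTest)
      m <- computeMetrics(pred, groups[sp$test],
                          labels = levels(groups))
      perRepeat <- rbind(perRepeat, data.frame(
        repeat_index = sp$repeat_index, accuracy = m$accuracy,
        macro_f1 = unname(m$macro["f1"])))
      lastMetrics <- m
      lastClassifier <- clf
    }
  }
  out <- list(perRepeat = perRepeat,
              meanAccuracy = mean(perRepeat$accuracy),
              sdAccuracy = if (nrow(perRepeat) > 1L) sd(perRepeat$accuracy)
                           else NA_real_,
              metrics = lastMetrics, rois = rois, config = config)
  if (config$model == "cvae") out$classifier <- lastClassifier
  out
}

#' Shapley attribution of a decoder prediction over a connectivity matrix
#'
#' `"roi-exact"` enumerates the 2^N ROI subsets exactly: an ROI absent
#' from a subset has all of its edges replaced by the background values.
#' `"edge-sampled"` attributes the N(N-1)/2 individual edges by
#' permutation sampling.  The explained output is the model probability of
#' `classIndex` (the predicted class when NULL).
#'
#' @param model a trained [DecoderModel-class].
#' @param conn the [ConnectivityMatrix-class] being explained.
#' @param background background connectivity (matrix or
#'   [ConnectivityMatrix-class]), typically the training-set mean.
#' @param mode `"roi-exact"` or `"edge-sampled"`.
#' @param classIndex output class to explain (default: predicted class).
#' @param nPermutations,seed sampling controls for `"edge-sampled"`.
#' @param adjacencyMode,featureMode graph construction, as in training.
#' @return a [ShapAttribution-class] (features named by ROI or `"A--B"`
#'   edge).
#' @export
explainConnectivity <- function(model, conn, background,
                                mode = c("roi-exact", "edge-sampled"),
                                classIndex = NULL, nPermutations = 100L,
                                seed = 1L, adjacencyMode = "abs",
                                featureMode = "rows") {
  mode <- match.arg(mode)
  bg <- if (is(background, "ConnectivityMatrix")) connValues(background)
        else as.matrix(background)
  x <- connValues(conn)
  rois <- roiNames(conn)
  n <- length(rois)
  if (is.null(classIndex)) {
    p0 <- decoderForward(model, list(graphFromConnectivity(
      conn, adjacencyMode, featureMode)))
    classIndex <- which.max(p0[1L, ])
  }
  predictOnMatrix <- function(v) {
    cm <- new("ConnectivityMatrix", values = v, kind = connKind(conn),
              subjectId = conn@subjectId, windowLabel = conn@windowLabel,
              roiNames = rois)
    g <- graphFromConnectivity(cm, adjacencyMode, featureMode)
    decoderForward(model, list(g))[1L, classIndex]
  }
  if (mode == "roi-exact") {
    valueFn <- function(s) {
      v <- bg
      v[s, s] <- x[s, s]
      v <- (v + base::t(v)) / 2
      diag(v) <- diag(x)
      predictOnMatrix(v)
    }
    shapExact(valueFn, n, featureNames = rois)
  } else {
    idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
    edgeNames <- paste0(rois[idx[, 1]], "--", rois[idx[, 2]])
    valueFn <- function(s) {
      v <- bg
      on <- idx[s, , drop = FALSE]
      v[on] <- x[on]
      v[on[, c(2, 1), drop = FALSE]] <- x[on]
      diag(v) <- diag(x)
      predictOnMatrix(v)
    }
    shapSample(valueFn, nrow(idx), nPermutations = nPermutations,
               seed = seed, featureNames = edgeNames)
  }
}
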