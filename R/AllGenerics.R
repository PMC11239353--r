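# Generics and accessor/show methods.  Slot access from user code should go
# through these.

#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))
#' @export
setGeneric("roiNetwork", function(x) standardGeneric("roiNetwork"))
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @export
setGeneric("windowSchedule", function(x) standardGeneric("windowSchedule"))
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))
#' @export
setGeneric("connKind", function(x) standardGeneric("connKind"))
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @export
setGeneric("cohortMeta", function(x) standardGeneric("cohortMeta"))
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @export
setGeneric("laplacian", function(x) standardGeneric("laplacian"))
#' @export
setGeneric("scaledLaplacian", function(x) standardGeneric("scaledLaplacian"))
#' @export
setGeneric("lambdaMax", function(x) standardGeneric("lambdaMax"))
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @export
setGeneric("shapValues", function(x) standardGeneric("shapValues"))

#' @describeIn RoiSet-class ROI labels.
#' @param x object.
#' @export
setMethod("roiNames", "RoiSet", function(x) x@names)
#' @describeIn RoiSet-class per-ROI network tags.
#' @export
setMethod("roiNetwork", "RoiSet", function(x) setNames(x@network, x@names))
#' @describeIn BoldTimeSeries-class ROI labels of the series.
#' @export
setMethod("roiNames", "BoldTimeSeries", function(x) x@roiSet@names)
#' @describeIn BoldTimeSeries-class the T x N BOLD matrix.
#' @export
setMethod("boldData", "BoldTimeSeries", function(x) x@data)
#' @describeIn BoldTimeSeries-class the event-window schedule.
#' @export
setMethod("windowSchedule", "BoldTimeSeries", function(x) x@windows)
#' @describeIn Cohort-class the common window schedule.
#' @export
setMethod("windowSchedule", "Cohort", function(x) x@windows)
#' @describeIn Cohort-class subject identifiers in cohort order.
#' @export
setMethod("subjectIds", "Cohort", function(x) as.character(x@meta$subject_id))
#' @describeIn Cohort-class subject metadata table.
#' @export
setMethod("cohortMeta", "Cohort", function(x) x@meta)
#' @describeIn Cohort-class ROI labels.
#' @export
setMethod("roiNames", "Cohort", function(x) x@roiSet@names)
#' @describeIn ConnectivityMatrix-class the N x N matrix.
#' @export
setMethod("connValues", "ConnectivityMatrix", function(x) x@values)
#' @describeIn ConnectivityMatrix-class `"FC"` or `"ISFC"`.
#' @export
setMethod("connKind", "ConnectivityMatrix", function(x) x@kind)
#' @describeIn ConnectivityMatrix-class ROI labels.
#' @export
setMethod("roiNames", "ConnectivityMatrix", function(x) x@roiNames)
#' @describeIn BrainGraph-class adjacency weights.
#' @export
setMethod("adjacency", "BrainGraph", function(x) x@adjacency)
#' @describeIn BrainGraph-class normalized Laplacian.
#' @export
setMethod("laplacian", "BrainGraph", function(x) x@laplacian)
#' @describeIn BrainGraph-class rescaled Laplacian.
#' @export
setMethod("scaledLaplacian", "BrainGraph", function(x) x@scaledLaplacian)
#' @describeIn BrainGraph-class largest Laplacian eigenvalue.
#' @export
setMethod("lambdaMax", "BrainGraph", function(x) x@lambdaMax)
#' @describeIn BrainGraph-class node-feature matrix.
#' @export
setMethod("nodeFeatures", "BrainGraph", function(x) x@nodeFeatures)
#' @describeIn ShapAttribution-class named Shapley values.
#' @export
setMethod("shapValues", "ShapAttribution", function(x) x@phi)

#' @describeIn Cohort-class number of subjects.
#' @export
setMethod("length", "Cohort", function(x) length(x@subjects))

#' @describeIn Cohort-class extract one subject's [BoldTimeSeries-class].
#' @param i subject index or id.
#' @export
setMethod("[[", "Cohort", function(x, i) {
  if (is.character(i)) i <- match(i, subjectIds(x))
  x@subjects[[i]]
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet with", length(object@names), "ROIs (",
      sum(object@network == "ToM"), "ToM /",
      sum(object@network == "Pain"), "Pain )\n")
})

setMethod("show", "BoldTimeSeries", function(object) {
  cat("BoldTimeSeries", object@subjectId, ":", nrow(object@data),
      "time points x", ncol(object@data), "ROIs, TR =",
      object@trSeconds, "s,", nrow(object@windows), "windows\n")
})

setMethod("show", "Cohort", function(object) {
  tab <- table(object@meta$group)
  cat("Cohort of", length(object@subjects), "subjects (",
      paste(names(tab), tab, sep = ":", collapse = ", "), ")\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  cat(object@kind, "matrix", nrow(object@values), "x", ncol(object@values),
      "( subject", object@subjectId, ", window", object@windowLabel, ")\n")
})

setMethod("show", "BrainGraph", function(object) {
  cat("BrainGraph with", nrow(object@adjacency), "nodes, lambda_max =",
      format(object@lambdaMax, digits = 4), ",",
      ncol(object@nodeFeatures), "node features\n")
})

setMethod("show", "ShapAttribution", function(object) {
  cat("ShapAttribution (", object@method, ") over", length(object@phi),
      "features; sum(phi) =", format(sum(object@phi), digits = 4), "\n")
})

setMethod("show", "DecoderModel", function(object) {
  cat("DecoderModel:", length(object@config$filters), "graph-conv block(s),",
      "K =", object@config$chebOrder, ",",
      if (object@trained) "trained" else "untrained", "\n")
})

setMethod("show", "VaeModel", function(object) {
  cat("VaeModel: input", object@config$nRoi, "x", object@config$nRoi,
      ", latent dim", object@config$latentDim, ",",
      if (object@trained) "trained" else "untrained", "\n")
})
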