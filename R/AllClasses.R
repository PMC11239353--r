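# S4 container classes.  Validity methods enforce the structural invariants
# that downstream numerics rely on; user code should go through the
# constructors and accessors rather than @ slots.

#' RoiSet: a labelled set of regions of interest
#'
#' Holds ROI labels, their network membership (`"ToM"` or `"Pain"`) and MNI
#' peak coordinates.  Coordinates are metadata only; no computation uses
#' them.
#'
#' @slot names character vector of unique ROI labels.
#' @slot network character vector, one of `"ToM"`/`"Pain"` per ROI.
#' @slot mni integer-valued matrix with one (x, y, z) row per ROI.
#' @seealso [defaultRoiSet()]
#' @export
setClass("RoiSet",
  representation(names = "character", network = "character", mni = "matrix"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@names)) msg <- c(msg, "ROI names must be unique")
    if (length(object@network) != length(object@names))
      msg <- c(msg, "network tag required for every ROI")
    if (!all(object@network %in% c("ToM", "Pain")))
      msg <- c(msg, "network tags must be 'ToM' or 'Pain'")
    if (nrow(object@mni) != length(object@names) || ncol(object@mni) != 3L)
      msg <- c(msg, "mni must be an n x 3 matrix")
    if (length(msg)) msg else TRUE
  })

#' BoldTimeSeries: one subject's ROI-by-time BOLD matrix
#'
#' @slot subjectId opaque subject identifier.
#' @slot data numeric T x N matrix (time points by ROIs), no missing values.
#' @slot windows data.frame event-window schedule with columns
#'   `label`, `state`, `start`, `end`, `description`.
#' @slot roiSet a [RoiSet-class] with N entries.
#' @slot trSeconds positive sampling interval in seconds (TR).
#' @export
setClass("BoldTimeSeries",
  representation(subjectId = "character", data = "matrix",
                 windows = "data.frame", roiSet = "RoiSet",
                 trSeconds = "numeric"),
  validity = function(object) {
    msg <- character()
    if (anyNA(object@data)) msg <- c(msg, "BOLD data must not contain NA")
    if (ncol(object@data) != length(object@roiSet@names))
      msg <- c(msg, "number of data columns must equal number of ROIs")
    if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
      msg <- c(msg, "trSeconds must be a single positive number")
    if (nrow(object@windows)) {
      w <- object@windows
      if (!all(c("label", "state", "start", "end") %in% colnames(w)))
        msg <- c(msg, "windows need columns label/state/start/end")
      else if (any(w$end > nrow(object@data)))
        msg <- c(msg, "window extends past the end of the series")
    }
    if (length(msg)) msg else TRUE
  })

#' Cohort: a set of subjects with behavioral metadata
#'
#' @slot subjects list of [BoldTimeSeries-class], one per subject.
#' @slot meta data.frame with columns `subject_id`, `age_group`, `group`,
#'   `n_correct` (pass: 5-6, inconsistent: 3-4, fail: 0-2 correct answers).
#' @slot roiSet the common [RoiSet-class].
#' @slot windows the common event-window schedule.
#' @slot config the generating configuration (empty for cohorts read from
#'   disk without one).
#' @export
setClass("Cohort",
  representation(subjects = "list", meta = "data.frame", roiSet = "RoiSet",
                 windows = "data.frame", config = "list"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@meta) != length(object@subjects))
      msg <- c(msg, "meta must have one row per subject")
    ids <- vapply(object@subjects, function(s) s@subjectId, character(1L))
    if (!identical(ids, as.character(object@meta$subject_id)))
      msg <- c(msg, "meta subject_id order must match subjects")
    if (!all(object@meta$group %in% c("pass", "inconsistent", "fail")))
      msg <- c(msg, "group labels must be pass/inconsistent/fail")
    if (length(msg)) msg else TRUE
  })

#' ConnectivityMatrix: one subject-by-window FC or ISFC matrix
#'
#' @slot values symmetric N x N numeric matrix with entries in \[-1, 1\];
#'   unit diagonal for kind `"FC"`.
#' @slot kind `"FC"` or `"ISFC"`.
#' @slot subjectId subject identifier.
#' @slot windowLabel window label the matrix was computed over.
#' @slot roiNames ROI labels in matrix order.
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", kind = "character",
                 subjectId = "character", windowLabel = "character",
                 roiNames = "character"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (!object@kind %in% c("FC", "ISFC")) msg <- c(msg, "kind must be FC or ISFC")
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    else {
      if (max(abs(v - base::t(v))) > 1e-12) msg <- c(msg, "values must be symmetric")
      if (max(abs(v)) > 1 + 1e-9) msg <- c(msg, "entries must lie in [-1, 1]")
      if (identical(object@kind, "FC") && max(abs(diag(v) - 1)) > 1e-9)
        msg <- c(msg, "FC diagonal must equal 1")
    }
    if (length(object@roiNames) != nrow(v))
      msg <- c(msg, "roiNames must match matrix dimension")
    if (length(msg)) msg else TRUE
  })

#' BrainGraph: adjacency, normalized Laplacian and node features
#'
#' `laplacian` is \eqn{L = I - D^{-1/2} A D^{-1/2}} and `scaledLaplacian`
#' is \eqn{(2/\lambda_{max}) L - I}, the operator Chebyshev filters act on.
#'
#' @slot adjacency nonnegative symmetric N x N weights, zero diagonal.
#' @slot laplacian normalized graph Laplacian (eigenvalues in \[0, 2\]).
#' @slot scaledLaplacian rescaled Laplacian (eigenvalues in \[-1, 1\]).
#' @slot lambdaMax largest Laplacian eigenvalue.
#' @slot nodeFeatures N x F numeric node-feature matrix.
#' @export
setClass("BrainGraph",
  representation(adjacency = "matrix", laplacian = "matrix",
                 scaledLaplacian = "matrix", lambdaMax = "numeric",
                 nodeFeatures = "matrix"),
  validity = function(object) {
    msg <- character()
    a <- object@adjacency
    if (any(diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (any(a < 0)) msg <- c(msg, "adjacency must be nonnegative")
    if (max(abs(a - base::t(a))) > 1e-9) msg <- c(msg, "adjacency must be symmetric")
    if (nrow(object@nodeFeatures) && nrow(object@nodeFeatures) != nrow(a))
      msg <- c(msg, "nodeFeatures must have one row per node")
    if (length(msg)) msg else TRUE
  })

#' ShapAttribution: Shapley values for one explained prediction
#'
#' Satisfies the efficiency axiom: `sum(phi) = fullValue - baseline`
#' (exactly in enumeration mode, up to Monte-Carlo error in sampled mode).
#'
#' @slot phi named numeric vector of Shapley values, one per feature.
#' @slot se per-feature standard errors (sampled mode; zeros for exact).
#' @slot baseline value of the empty feature set.
#' @slot fullValue value of the complete feature set.
#' @slot method `"exact"` or `"sampled"`.
#' @export
setClass("ShapAttribution",
  representation(phi = "numeric", se = "numeric", baseline = "numeric",
                 fullValue = "numeric", method = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@se) != length(object@phi))
      msg <- c(msg, "se must match phi length")
    if (!object@method %in% c("exact", "sampled"))
      msg <- c(msg, "method must be exact or sampled")
    if (length(msg)) msg else TRUE
  })

#' DecoderModel: a trained (or initialized) graph-convolutional state decoder
#'
#' @slot config the decoder configuration list (see [decoderConfig()]).
#' @slot params list of per-block Chebyshev filter weights, biases,
#'   batch-norm parameters and the dense softmax head.
#' @slot history data.frame of per-epoch training/validation loss.
#' @slot classes class labels in output order.
#' @slot trained logical flag.
#' @export
setClass("DecoderModel",
  representation(config = "list", params = "list", history = "data.frame",
                 classes = "character", trained = "logical"))

#' VaeModel: a convolutional variational autoencoder
#'
#' @slot config configuration list (see [vaeConfig()]).
#' @slot params encoder and decoder parameter tensors.
#' @slot maps cached convolution index maps for the input geometry.
#' @slot history per-epoch loss components.
#' @slot trained logical flag.
#' @export
setClass("VaeModel",
  representation(config = "list", params = "list", maps = "list",
                 history = "data.frame", trained = "logical"))

#' LatentClassifier: sigmoid one-vs-all head on VAE latent codes
#'
#' @slot weights latent_dim x n_groups weight matrix.
#' @slot bias per-group bias.
#' @slot center,scale standardization applied to latent codes.
#' @slot classes group labels in output order.
#' @slot history per-epoch binary cross-entropy.
#' @export
setClass("LatentClassifier",
  representation(weights = "matrix", bias = "numeric", center = "numeric",
                 scale = "numeric", classes = "character",
                 history = "data.frame"))
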