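# Delimited-text serialization of cohorts: one time-series file per
# subject, a metadata table, a window schedule, an ROI table and a JSON
# manifest tying them together.

#' Write a cohort to a directory of delimited text files
#'
#' Layout: `manifest.json`, `metadata.tsv`, `windows.tsv`, `roi_set.tsv`
#' and one `series/<subject_id>.tsv` per subject (rows = time points,
#' columns = ROI labels).  `readCohort()` restores the cohort;
#' write-then-read is an identity up to numeric text precision.
#'
#' @param cohort a [Cohort-class].
#' @param directory output directory (created if missing).
#' @param sep field separator; tab by default, `","` accepted.
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, directory, sep = "\t") {
  stopifnot(is(cohort, "Cohort"))
  dir.create(file.path(directory, "series"), recursive = TRUE,
             showWarnings = FALSE)
  wt <- function(x, f) write.table(
    x, file.path(directory, f), sep = sep, quote = FALSE, row.names = FALSE)
  wt(cohort@meta, "metadata.tsv")
  wt(cohort@windows, "windows.tsv")
  rs <- cohort@roiSet
  wt(data.frame(name = rs@names, network = rs@network, rs@mni), "roi_set.tsv")
  for (s in cohort@subjects)
    wt(as.data.frame(s@data), file.path("series", paste0(s@subjectId, ".tsv")))
  manifest <- list(
    format = "fcdecode-cohort/1",
    package_version = as.character(utils::packageVersion("fcdecode")),
    sep = sep,
    tr_seconds = cohort@subjects[[1]]@trSeconds,
    n_subjects = length(cohort@subjects),
    subjects = subjectIds(cohort))
  mp <- file.path(directory, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), mp)
  invisible(mp)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param directory directory holding a cohort manifest.
#' @return a [Cohort-class] (with an empty `config`).
#' @export
readCohort <- function(directory) {
  mp <- file.path(directory, "manifest.json")
  if (!file.exists(mp))
    stop("no manifest: '", mp, "' does not exist; not a cohort directory",
         call. = FALSE)
  manifest <- jsonlite::fromJSON(readLines(mp, warn = FALSE))
  sep <- manifest$sep %||% "\t"
  rd <- function(f) {
    path <- file.path(directory, f)
    out <- tryCatch(read.delim(path, sep = sep, check.names = FALSE,
                               stringsAsFactors = FALSE),
                    error = function(e) stop("parse error in '", path, "': ",
                                             conditionMessage(e),
                                             call. = FALSE))
    out
  }
  meta <- rd("metadata.tsv")
  windows <- validateWindows(rd("windows.tsv"))
  roiTab <- rd("roi_set.tsv")
  rs <- newRoiSet(roiTab$name, roiTab$network,
                  as.matrix(roiTab[, c("x", "y", "z")]))
  files <- list.files(file.path(directory, "series"), pattern = "\\.tsv$")
  onDisk <- sub("\\.tsv$", "", files)
  missingSeries <- setdiff(meta$subject_id, onDisk)
  if (length(missingSeries))
    stop("consistency error: metadata lists subject(s) with no series file: ",
         paste(missingSeries, collapse = ", "), call. = FALSE)
  extra <- setdiff(onDisk, meta$subject_id)
  if (length(extra))
    stop("consistency error: series file(s) for subject(s) missing from ",
         "metadata: ", paste(extra, collapse = ", "), call. = FALSE)
  tr <- manifest$tr_seconds %||% 2
  subjects <- lapply(meta$subject_id, function(id) {
    d <- as.matrix(rd(file.path("series", paste0(id, ".tsv"))))
    if (!identical(colnames(d), rs@names))
      stop("parse error in series file for ", id,
           ": columns do not match the ROI table", call. = FALSE)
    new("BoldTimeSeries", subjectId = as.character(id), data = d,
        windows = windows, roiSet = rs, trSeconds = tr)
  })
  new("Cohort", subjects = subjects,
      meta = data.frame(meta, stringsAsFactors = FALSE),
      roiSet = rs, windows = windows, config = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
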