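#' Default 12-region ROI set (6 ToM + 6 Pain)
#'
#' The six Theory-of-Mind network regions (PCC, bilateral TPJ, vmPFC,
#' Precuneus, dmPFC) and six pain-network regions (bilateral MFG, bilateral
#' anterior insula, bilateral secondary sensory cortex) with their MNI peak
#' coordinates.  Coordinates are carried as metadata only.
#'
#' @return a [RoiSet-class] with 12 entries.
#' @export
#' @examples
#' rs <- defaultRoiSet()
#' table(roiNetwork(rs))
defaultRoiSet <- function() {
  tab <- data.frame(
    name = c("PCC", "LTPJ", "RTPJ", "vmPFC", "Precuneus", "dmPFC",
             "RMFG", "LMFG", "LII", "RII", "LSSC", "RSSC"),
    network = rep(c("ToM", "Pain"), each = 6L),
    x = c(0, -46, 46, 4, 0, -10, 36, -36, -40, 39, -39, 39),
    y = c(-52, -68, -68, 48, -49, 58, 38, 38, 22, 23, -15, -15),
    z = c(18, 32, 32, -4, 40, 24, 40, 40, 0, -4, 18, 18))
  newRoiSet(tab$name, tab$network, as.matrix(tab[, c("x", "y", "z")]))
}

#' Construct a RoiSet
#'
#' @param names unique ROI labels.
#' @param network per-ROI network tag, `"ToM"` or `"Pain"`.
#' @param mni optional n x 3 matrix of MNI coordinates (metadata only).
#' @return a [RoiSet-class].
#' @export
newRoiSet <- function(names, network, mni = matrix(0L, length(names), 3L)) {
  rownames(mni) <- names
  colnames(mni) <- c("x", "y", "z")
  new("RoiSet", names = as.character(names), network = as.character(network),
      mni = mni)
}

#' Default event-window schedule: 5 ToM + 5 Pain windows, 168 time points
#'
#' Ten short movie-event windows (TR = 2 s): five scenes engaging the ToM
#' network (T1-T5) and five pain scenes (P1-P5), alternating in time.  Only
#' the total length (168 TRs) and the minimum event duration (> 8 s, i.e. at
#' least 5 TRs) are constrained by the experimental design; individual
#' window lengths default to an even {17, 17, 17, 17, 16} split per state.
#'
#' @param lengthsToM,lengthsPain integer window lengths (TR units), each
#'   >= 5; must sum to 168 with the defaults.
#' @return data.frame with columns `label`, `state`, `start`, `end`,
#'   `description`.
#' @export
#' @examples
#' w <- defaultWindows()
#' sum(w$end - w$start + 1L)  # 168
defaultWindows <- function(lengthsToM = c(17L, 17L, 17L, 17L, 16L),
                           lengthsPain = c(17L, 17L, 17L, 17L, 16L)) {
  stopifnot(length(lengthsToM) == 5L, length(lengthsPain) == 5L,
            all(lengthsToM >= 5L), all(lengthsPain >= 5L))
  descToM <- c("Peck flies away to happy cloud",
               "Peck caught gazing at happy clouds",
               "Baby crying, then happy",
               "Peck dons gear to show why he left",
               "Pan from happy clouds to lonely cloud (Gus)")
  descPain <- c("Gus pulls porcupine spines from Peck's head",
                "Alligator biting Peck",
                "Peck tossing porcupine",
                "Cloud makes animals (lightning)",
                "Gus makes alligator (lightning)")
  # alternate T1, P1, T2, P2, ... to mimic interleaved movie events
  lab <- as.vector(rbind(paste0("T", 1:5), paste0("P", 1:5)))
  state <- rep(c("ToM", "Pain"), 5L)
  len <- as.vector(rbind(lengthsToM, lengthsPain))
  desc <- as.vector(rbind(descToM, descPain))
  end <- cumsum(len)
  data.frame(label = lab, state = state,
             start = c(1L, head(end, -1L) + 1L), end = end,
             description = desc, stringsAsFactors = FALSE)
}

# Validate a window schedule data.frame (used by readers).
validateWindows <- function(w) {
  stopifnot(is.data.frame(w),
            all(c("label", "state", "start", "end") %in% colnames(w)))
  if (any(w$end <= w$start)) stop("window end must exceed start", call. = FALSE)
  if (any(w$end - w$start + 1L < 5L))
    stop("every window must span at least 5 time points (> 8 s at TR 2 s)",
         call. = FALSE)
  invisible(w)
}
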