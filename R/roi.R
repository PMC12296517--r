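#' Default region-of-interest electrode map
#'
#' Six scalp areas spanning the fronto-parieto-occipital sensorimotor
#' network, each defined by a fixed set of 10-10 electrode labels:
#' dorsolateral prefrontal cortex (DLPFC), supplementary/premotor areas
#' (SMA/PMA), primary motor cortex (M1), primary somatosensory cortex (S1),
#' posterior parietal cortex (PPC) and parieto-occipital cortex (POC).
#' 31 electrodes in total.
#'
#' The POC labels PO1/PO2 are kept as-is even though many 10-10 montages
#' use PO3/PO4; importers of external recordings can remap labels before
#' analysis. The synthetic generator emits matching labels.
#'
#' @return Named list of character vectors (ordered areas), class `roi_map`.
#' @examples
#' roi <- default_roi_map()
#' lengths(roi)
#' @export
default_roi_map <- function() {
  roi <- list(
    "DLPFC"   = c("F5", "F1", "AF3", "AF4", "F2", "F6"),
    "SMA/PMA" = c("FC4", "FC2", "FCz", "FC1", "FC3"),
    "M1"      = c("C5", "C1", "Cz", "C4", "C6"),
    "S1"      = c("CP3", "CP1", "CPz", "CP2", "CP4"),
    "PPC"     = c("P3", "P1", "Pz", "P2", "P4"),
    "POC"     = c("PO1", "PO2", "O1", "Oz", "O2")
  )
  class(roi) <- "roi_map"
  roi
}

#' Validate a region-of-interest map
#'
#' Checks that areas are disjoint, that each area used for within-area
#' connectivity has at least two electrodes, and (optionally) that every
#' electrode is present in a recording's channel labels.
#'
#' @param roi named list of electrode-label vectors.
#' @param channel_labels optional character vector of available channels.
#' @return `roi` invisibly (with class `roi_map`), or an error.
#' @export
validate_roi_map <- function(roi, channel_labels = NULL) {
  if (is.null(names(roi)) || any(names(roi) == ""))
    stop("all ROI areas must be named")
  labs <- unlist(roi, use.names = FALSE)
  if (anyDuplicated(labs))
    stop("ROI areas must be disjoint; duplicated electrode(s): ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (any(lengths(roi) < 2))
    stop("each ROI area needs >= 2 electrodes (within-area connectivity ",
         "is undefined otherwise): ",
         paste(names(roi)[lengths(roi) < 2], collapse = ", "))
  if (!is.null(channel_labels)) {
    missing <- setdiff(labs, channel_labels)
    if (length(missing) > 0)
      stop("ROI electrodes absent from the recording: ",
           paste(missing, collapse = ", "))
  }
  class(roi) <- "roi_map"
  invisible(roi)
}

#' All ROI electrodes, in area order
#' @param roi an `roi_map`.
#' @return Character vector of electrode labels.
#' @export
roi_channels <- function(roi) unlist(roi, use.names = FALSE)

# Unordered channel-pair enumeration shared across the package:
# combn(n, 2) column order, i.e. (1,2), (1,3), ..., (2,3), ...
pair_index <- function(n_ch) combn(n_ch, 2)

# For each pair of channel labels, the area indices (a_i, a_j) it connects.
# Returns list(pairs = 2 x n_pairs channel index matrix,
#              labels = 2 x n_pairs channel label matrix,
#              areas = 2 x n_pairs area index matrix (a_i <= a_j))
pair_map <- function(roi, channel_labels = NULL) {
  chans <- roi_channels(roi)
  if (is.null(channel_labels)) channel_labels <- chans
  idx <- match(chans, channel_labels)
  if (anyNA(idx))
    stop("ROI electrodes absent from the recording: ",
         paste(chans[is.na(idx)], collapse = ", "))
  area_of <- rep(seq_along(roi), lengths(roi))
  pr <- pair_index(length(chans))          # indices into `chans`
  a <- rbind(area_of[pr[1, ]], area_of[pr[2, ]])
  # row of each ROI pair in a pair_connectivity enumerated over
  # channel_labels (combn order over sorted channel indices)
  n_lab <- length(channel_labels)
  ii <- pmin(idx[pr[1, ]], idx[pr[2, ]])
  jj <- pmax(idx[pr[1, ]], idx[pr[2, ]])
  rows <- (ii - 1L) * n_lab - ii * (ii - 1L) / 2L + (jj - ii)
  list(
    pairs = matrix(idx[pr], nrow = 2),     # indices into channel_labels
    labels = matrix(chans[pr], nrow = 2),
    areas = a,
    rows = as.integer(rows),
    area_names = names(roi)
  )
}
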