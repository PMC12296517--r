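#' Area-level network matrix for one time window
#'
#' Averages the windowed pairwise rPLV into a symmetric area adjacency
#' matrix: the diagonal holds the mean over all unordered electrode pairs
#' within an area, the off-diagonal `(a, b)` the mean over all cross-area
#' electrode pairs. Electrode self-pairs do not exist in PLV and are
#' excluded. The pairwise rPLV is first time-averaged over the half-open
#' window, then pair-averaged per cell (orders commute for plain means; the
#' order is fixed for reproducibility).
#'
#' @param pc a `pair_connectivity` (see [subject_connectivity()]).
#' @param roi an `roi_map`; defaults to [default_roi_map()].
#' @param window half-open ms window `c(start, end)`.
#' @return An `area_matrix`: list with the 6x6 `matrix`, the length-21
#'   `feature_vector` (row-major upper triangle including the diagonal),
#'   `window`, `subject_id`, `group`.
#' @export
area_adjacency <- function(pc, roi = default_roi_map(), window) {
  stopifnot(inherits(pc, "pair_connectivity"))
  validate_roi_map(roi, pc$channel_labels)
  pm <- pair_map(roi, pc$channel_labels)
  w <- pair_window_mean(pc, window)[pm$rows]  # per ROI pair, pair_map order
  n_area <- length(roi)
  mat <- matrix(NA_real_, n_area, n_area,
                dimnames = list(names(roi), names(roi)))
  for (a in seq_len(n_area)) {
    for (b in a:n_area) {
      sel <- pm$areas[1, ] == a & pm$areas[2, ] == b
      mat[a, b] <- mat[b, a] <- mean(w[sel])
    }
  }
  structure(
    list(matrix = mat,
         feature_vector = feature_vector(mat),
         window = window,
         subject_id = pc$subject_id,
         group = pc$group),
    class = "area_matrix"
  )
}

# Windowed time-average of rPLV for the ROI electrode pairs, in the
# pair_map (combn over ROI channels) order. Errors if the window holds no
# evaluated samples.
pair_window_mean <- function(pc, window, roi = NULL) {
  cols <- which(pc$time >= window[1] - 1e-9 & pc$time < window[2] - 1e-9)
  if (length(cols) == 0)
    stop(sprintf("window [%g, %g) ms holds no evaluated samples",
                 window[1], window[2]))
  rowMeans(pc$rplv[, cols, drop = FALSE])
}

#' Row-major upper-triangle feature vector of a symmetric matrix
#'
#' Enumeration order is fixed: (1,1), (1,2), ..., (1,k), (2,2), ...,
#' (k,k) — 21 entries for a 6x6 matrix (6 within-area + 15 between-area).
#' [features_to_matrix()] inverts it losslessly.
#'
#' @param mat symmetric numeric matrix.
#' @return Named numeric vector of the unique entries.
#' @export
feature_vector <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  k <- nrow(mat)
  idx <- which(upper.tri(mat, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  v <- mat[idx]
  if (!is.null(rownames(mat)))
    names(v) <- paste(rownames(mat)[idx[, 1]], colnames(mat)[idx[, 2]],
                      sep = "~")
  v
}

#' Rebuild the symmetric matrix from a feature vector
#' @param v feature vector in [feature_vector()] order.
#' @param area_names optional dimnames.
#' @return Symmetric k x k matrix.
#' @export
features_to_matrix <- function(v, area_names = NULL) {
  k <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (k != round(k))
    stop("length ", length(v), " is not a triangular number")
  k <- as.integer(k)
  mat <- matrix(0, k, k)
  pos <- 1L
  for (i in seq_len(k)) for (j in i:k) {
    mat[i, j] <- mat[j, i] <- v[pos]
    pos <- pos + 1L
  }
  if (!is.null(area_names)) dimnames(mat) <- list(area_names, area_names)
  mat
}

#' Split a window into equal contiguous subwindows
#'
#' @param window half-open ms window.
#' @param n number of subwindows; the window length must be divisible by
#'   `n`.
#' @return List of `n` half-open ms windows.
#' @examples
#' subwindows(c(0, 500), 5)
#' @export
subwindows <- function(window, n) {
  len <- diff(window)
  if (abs(len / n - round(len / n)) > 1e-9)
    stop("window length ", len, " ms is not divisible into ", n,
         " equal subwindows")
  step <- len / n
  lapply(seq_len(n) - 1L, function(i)
    c(window[1] + i * step, window[1] + (i + 1) * step))
}

#' Mean network rPLV over a window
#'
#' Average phase synchronization across all electrode pairs (465 pairs for
#' the 31-electrode ROI set) within a half-open time window.
#'
#' @inheritParams area_adjacency
#' @return Scalar mean rPLV.
#' @export
mean_network_rplv <- function(pc, window) {
  stopifnot(inherits(pc, "pair_connectivity"))
  mean(pair_window_mean(pc, window))
}

#' Area-level rPLV time courses
#'
#' Collapses the pairwise rPLV to the 21 unique area connections (feature
#' order of [feature_vector()]) at every evaluated sample — the input for
#' pointwise significance maps, Euclidean distance and PCA time courses.
#'
#' @inheritParams area_adjacency
#' @return 21 x n_samples matrix with connection names as rownames;
#'   attribute `time` carries the sample times (ms).
#' @export
area_timecourse <- function(pc, roi = default_roi_map()) {
  stopifnot(inherits(pc, "pair_connectivity"))
  validate_roi_map(roi, pc$channel_labels)
  pm <- pair_map(roi, pc$channel_labels)
  n_area <- length(roi)
  conn <- matrix(NA_real_, n_area * (n_area + 1) / 2, ncol(pc$rplv))
  cn <- character(nrow(conn))
  pos <- 1L
  for (a in seq_len(n_area)) for (b in a:n_area) {
    sel <- pm$rows[pm$areas[1, ] == a & pm$areas[2, ] == b]
    conn[pos, ] <- colMeans(pc$rplv[sel, , drop = FALSE])
    cn[pos] <- paste(names(roi)[a], names(roi)[b], sep = "~")
    pos <- pos + 1L
  }
  rownames(conn) <- cn
  attr(conn, "time") <- pc$time
  conn
}
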