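#' Weighted electrode graph from a windowed connectivity estimate
#'
#' Time-averages the pairwise rPLV over a half-open window and uses the
#' result as edge weights of an undirected graph on the ROI electrodes.
#' Negative windowed rPLV values carry no path-length interpretation and
#' are clipped to 0 (edge absent).
#'
#' @inheritParams area_adjacency
#' @return A `plv_graph`: list with the symmetric nonnegative `adjacency`
#'   matrix (zero diagonal) and the node `labels`.
#' @export
graph_from_window <- function(pc, roi = default_roi_map(), window) {
  stopifnot(inherits(pc, "pair_connectivity"))
  validate_roi_map(roi, pc$channel_labels)
  pm <- pair_map(roi, pc$channel_labels)
  w <- pair_window_mean(pc, window)[pm$rows]
  labs <- roi_channels(roi)
  n <- length(labs)
  adj <- matrix(0, n, n, dimnames = list(labs, labs))
  # pm$pairs indexes channel_labels; rebuild in ROI-channel order
  pr <- pair_index(n)
  adj[t(pr)] <- pmax(w, 0)
  adj[t(pr[2:1, , drop = FALSE])] <- pmax(w, 0)
  plv_graph(adj, labs)
}

#' Construct a weighted graph from an adjacency matrix
#'
#' @param adjacency symmetric numeric matrix with nonnegative weights and
#'   zero diagonal (the diagonal is zeroed if not).
#' @param labels optional node labels.
#' @return A `plv_graph`.
#' @export
plv_graph <- function(adjacency, labels = rownames(adjacency)) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (any(adjacency < 0)) stop("edge weights must be >= 0")
  if (max(abs(adjacency - t(adjacency))) > 1e-12)
    stop("adjacency must be symmetric")
  diag(adjacency) <- 0
  if (is.null(labels)) labels <- as.character(seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adjacency = adjacency, labels = labels),
            class = "plv_graph")
}

as_plv_graph <- function(g) {
  if (inherits(g, "plv_graph")) g else plv_graph(as.matrix(g))
}

#' Global efficiency of a weighted graph
#'
#' Mean over ordered node pairs of the inverse shortest-path length,
#' `E_glob = 1 / (N (N - 1)) * sum_{i != j} 1 / L_ij`. In `"weighted"`
#' mode path lengths accumulate edge distances `1 / w`; in `"binary"` mode
#' they are hop counts on the positive-weight skeleton (matching the common
#' library default that ignores weights). Disconnected pairs contribute 0.
#'
#' Note weighted efficiency scales with the weights: multiplying all
#' weights by `c > 0` multiplies it by `c`. Binary efficiency is
#' scale-free and lies in `[0, 1]`.
#'
#' @param g a `plv_graph` or adjacency matrix.
#' @param mode `"binary"` (default) or `"weighted"`.
#' @return Scalar efficiency.
#' @examples
#' g <- plv_graph(matrix(1, 4, 4) - diag(4))
#' global_efficiency(g)  # complete unit graph -> 1
#' @export
global_efficiency <- function(g, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  g <- as_plv_graph(g)
  n <- nrow(g$adjacency)
  if (n < 2) stop("global efficiency needs >= 2 nodes")
  D <- shortest_path_lengths(g$adjacency, mode)
  off <- D[row(D) != col(D)]
  sum(ifelse(is.finite(off), 1 / off, 0)) / (n * (n - 1))
}

# All-pairs shortest path lengths on the positive-weight skeleton.
# mode = "binary": unit hop lengths; "weighted": edge distance 1/w.
shortest_path_lengths <- function(adj, mode) {
  pos <- adj > 0
  gi <- igraph::graph_from_adjacency_matrix(
    pos * 1, mode = "undirected", diag = FALSE)
  if (mode == "binary") {
    igraph::distances(gi)
  } else {
    ed <- igraph::as_edgelist(gi, names = FALSE)
    wts <- adj[ed]
    igraph::distances(gi, weights = 1 / wts)
  }
}

#' Average clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient. `"binary"` mode is
#' the triangle fraction among each node's neighbors on the positive-weight
#' skeleton; `"weighted"` mode is the geometric-mean (intensity) variant on
#' weights rescaled by the maximum weight,
#' `C_i = 1 / (k_i (k_i - 1)) * sum_{j,h} (w_ij w_ih w_jh)^(1/3)`.
#' Nodes with degree < 2 contribute 0.
#'
#' @inheritParams global_efficiency
#' @return Scalar in `[0, 1]`.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' average_clustering(plv_graph(tri))  # closed triangle -> 1
#' @export
average_clustering <- function(g, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  g <- as_plv_graph(g)
  adj <- g$adjacency
  n <- nrow(adj)
  if (n < 1) stop("average clustering needs >= 1 node")
  sk <- (adj > 0) * 1
  k <- rowSums(sk)
  denom <- k * (k - 1)
  if (mode == "binary") {
    tri <- diag(sk %*% sk %*% sk)
  } else {
    if (max(adj) > 0) {
      w13 <- (adj / max(adj))^(1 / 3)
      tri <- diag(w13 %*% w13 %*% w13)
    } else {
      tri <- rep(0, n)
    }
  }
  ci <- ifelse(denom > 0, tri / denom, 0)
  mean(ci)
}

#' Graph summaries for one subject and window
#'
#' Convenience wrapper building the windowed graph and returning global
#' efficiency and average clustering in both binary and weighted modes.
#'
#' @inheritParams area_adjacency
#' @return One-row data.frame: subject, group, window bounds, e_glob and
#'   clustering per mode.
#' @export
graph_summary <- function(pc, roi = default_roi_map(), window) {
  g <- graph_from_window(pc, roi, window)
  data.frame(
    subject_id = pc$subject_id %||% NA_character_,
    group = pc$group %||% NA_character_,
    window_start = window[1], window_end = window[2],
    e_glob_binary = global_efficiency(g, "binary"),
    e_glob_weighted = global_efficiency(g, "weighted"),
    clustering_binary = average_clustering(g, "binary"),
    clustering_weighted = average_clustering(g, "weighted"),
    stringsAsFactors = FALSE
  )
}
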