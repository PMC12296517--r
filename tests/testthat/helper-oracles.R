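# Shared fixtures and independent oracles for the test suite.

# Small, fast cohort configurations --------------------------------------

tiny_config <- function(...) {
  args <- list(n_per_group = 2, n_trials_per_side = 4,
               epoch_span = c(-3700, -2100))
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

cue_config <- function(...) {
  # full trial count, epoch truncated after the post-S1 analysis window
  args <- list(epoch_span = c(-3700, -2100))
  over <- list(...)
  args[names(over)] <- over
  do.call(cohort_config, args)
}

# A pair_connectivity stub with prescribed pairwise rPLV values ----------

fake_pc <- function(values, labels = roi_channels(default_roi_map()),
                    n_t = 10, time0 = -3200) {
  n <- length(labels)
  rplv <- matrix(values, n * (n - 1) / 2, n_t)
  pm <- combn(n, 2)
  structure(
    list(rplv = rplv, pairs = pm,
         pair_labels = matrix(labels[pm], nrow = 2),
         time = seq(time0, by = 5, length.out = n_t),
         channel_labels = labels,
         subject_id = "fake", group = "CO",
         unusable = logical(nrow(rplv))),
    class = "pair_connectivity"
  )
}

# Brute-force PLV oracle: direct complex sums from phase matrices --------

plv_bruteforce <- function(phases_i, phases_j) {
  n_s <- nrow(phases_i); n_tr <- ncol(phases_i)
  out <- numeric(n_s)
  for (t in seq_len(n_s)) {
    acc <- 0 + 0i
    for (n in seq_len(n_tr))
      acc <- acc + exp(-1i * (phases_i[t, n] - phases_j[t, n]))
    out[t] <- Mod(acc) / n_tr
  }
  out
}

# Exhaustive shortest paths (n <= ~7): enumerate all simple paths --------

exhaustive_distances <- function(adj, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  n <- nrow(adj)
  edge_len <- function(i, j) {
    if (adj[i, j] <= 0) return(Inf)
    if (mode == "binary") 1 else 1 / adj[i, j]
  }
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  # depth-first over all simple paths
  visit <- function(path, len) {
    i <- path[length(path)]
    s <- path[1]
    if (len < best[s, i]) best[s, i] <<- len
    for (j in seq_len(n)) {
      if (!(j %in% path) && is.finite(edge_len(i, j)))
        visit(c(path, j), len + edge_len(i, j))
    }
  }
  for (s in seq_len(n)) visit(s, 0)
  best
}

exhaustive_efficiency <- function(adj, mode = "binary") {
  n <- nrow(adj)
  D <- exhaustive_distances(adj, mode)
  off <- D[row(D) != col(D)]
  sum(ifelse(is.finite(off), 1 / off, 0)) / (n * (n - 1))
}

# Exact Mann-Whitney p by enumeration of all rank arrangements ------------

mwu_enumeration_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  pool <- c(x, y)
  picks <- combn(n1 + n2, n1)
  ud <- apply(picks, 2, function(ix) u_of(pool[ix], pool[-ix]))
  min(1, 2 * min(mean(ud <= u_obs + 1e-12), mean(ud >= u_obs - 1e-12)))
}

# Hand-rolled BH step-up ---------------------------------------------------

bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}
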