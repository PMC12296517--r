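#' Across-trial phase-locking value time course
#'
#' PLV(t) is the modulus of the trial-mean unit phasor of the phase
#' difference between two signals: `|1/N sum_n exp(-i (phi_i - phi_j))|`.
#' It lies in `[0, 1]` (1 = perfectly consistent phase relation across
#' trials) and is symmetric in the two inputs.
#'
#' @param phases_i,phases_j samples x trials matrices of instantaneous
#'   phase, radians.
#' @return Numeric vector, one PLV per sample.
#' @examples
#' ph <- matrix(runif(40, -pi, pi), 10, 4)
#' plv_timecourse(ph, ph + pi / 3)  # constant offset -> all 1
#' @export
plv_timecourse <- function(phases_i, phases_j) {
  phases_i <- as.matrix(phases_i); phases_j <- as.matrix(phases_j)
  if (!identical(dim(phases_i), dim(phases_j)))
    stop("phase matrices must have identical dimensions")
  n <- ncol(phases_i)
  if (n < 2) stop("PLV requires at least 2 trials")
  Mod(rowMeans(exp(-1i * (phases_i - phases_j))))
}

#' Baseline-normalized relative PLV
#'
#' Per frequency bin, `rPLV(t) = (PLV(t) - b) / b` with `b` the mean PLV
#' over the pre-stimulus baseline window; the per-bin rPLV series are then
#' averaged across the band. By construction the time-mean of rPLV over the
#' baseline window is 0. A baseline mean below `eps` makes the pair
#' unusable: the result is all-NA with attribute `unusable = TRUE` (and a
#' warning) instead of a silent near-zero division.
#'
#' @param plv samples x frequencies matrix (or vector) of PLV in `[0, 1]`.
#' @param time_axis sample times, ms relative to S2.
#' @param baseline half-open baseline window `c(start, end)` ms.
#' @param eps numeric floor for the baseline mean.
#' @return Band-averaged rPLV vector (one per sample), with attribute
#'   `baseline_mean` (per-frequency baseline means).
#' @examples
#' plv <- matrix(0.4, 50, 2)
#' rp <- relative_plv(plv, seq(-3700, by = 5, length.out = 50),
#'                    baseline = c(-3700, -3600))
#' all(rp == 0)
#' @export
relative_plv <- function(plv, time_axis, baseline = c(-3700, -3200),
                         eps = 1e-6) {
  plv <- as.matrix(plv)
  stopifnot(length(time_axis) == nrow(plv))
  bidx <- window_samples(baseline, time_axis)
  b <- colMeans(plv[bidx, , drop = FALSE])
  if (any(b < eps)) {
    warning("baseline PLV mean below ", eps, "; pair flagged unusable")
    out <- rep(NA_real_, nrow(plv))
    attr(out, "baseline_mean") <- b
    attr(out, "unusable") <- TRUE
    return(out)
  }
  rp <- sweep(sweep(plv, 2, b, "-"), 2, b, "/")
  out <- rowMeans(rp)
  attr(out, "baseline_mean") <- b
  attr(out, "unusable") <- FALSE
  out
}

# R reference implementation of the pairwise PLV kernel (direct complex
# sums); used as the independent cross-check of the compiled kernel.
plv_pairs_ref <- function(coef, n_ch, n_tr, floor_amp = 1e-12) {
  n_out <- nrow(coef)
  pr <- pair_index(n_ch)
  out <- matrix(0, ncol(pr), n_out)
  for (t in seq_len(n_out)) {
    z <- matrix(coef[t, ], n_ch, n_tr)
    m <- Mod(z)
    z <- ifelse(m < floor_amp, 0 + 0i, z / m)
    for (p in seq_len(ncol(pr))) {
      out[p, t] <- Mod(sum(z[pr[1, p], ] * Conj(z[pr[2, p], ]))) / n_tr
    }
  }
  out
}

#' Pairwise rPLV time courses for one subject
#'
#' The per-subject connectivity pipeline: Morlet phase at the requested
#' frequencies, across-trial PLV for every unordered channel pair, baseline
#' normalization to rPLV per 1-Hz bin, band averaging, and (by default)
#' averaging of the per-condition (left/right response side) rPLV series.
#' Only valid trials (correct response within 1.5 s) enter.
#'
#' When `windows` is given, phase and PLV are evaluated only on the
#' baseline window plus the listed analysis windows (on a grid of every
#' `sample_step`-th sample), which keeps cohort-scale simulations cheap;
#' with `windows = NULL` the full epoch is evaluated.
#'
#' @param epochs an `epoch_set`.
#' @param freqs analysis frequencies, Hz.
#' @param n_cycles Morlet cycles.
#' @param baseline baseline window, ms, half-open.
#' @param windows optional list of half-open ms windows to evaluate
#'   (e.g. `list(S1 = c(-3200, -2700), S2 = c(0, 500))`).
#' @param sample_step evaluate every k-th sample of each window (1 = all).
#' @param eps baseline-mean floor; pairs below it are flagged unusable
#'   (rPLV set NA) and reported in the `unusable` field.
#' @param by_condition compute rPLV per response side, then average the
#'   sides (set `FALSE` to pool all valid trials into one PLV).
#' @param keep_plv also return the band-mean PLV matrix.
#' @return A `pair_connectivity`: `rplv` (n_pairs x n_eval samples,
#'   band-averaged), pair labels (2 x n_pairs, `combn` order), evaluated
#'   `time` (ms), `baseline_cols`, per-frequency edge-`valid` flags,
#'   `unusable` pair flags, and bookkeeping fields.
#' @examples
#' cfg <- cohort_config(n_per_group = 2, n_trials_per_side = 8,
#'                      epoch_span = c(-3700, -2100))
#' es <- generate_epoch_set("CO01", "CO", cfg, seed = 2)
#' pc <- subject_connectivity(es, windows = list(S1 = c(-3200, -2700)))
#' dim(pc$rplv)
#' @export
subject_connectivity <- function(epochs, freqs = 4:7, n_cycles = 5,
                                 baseline = c(-3700, -3200),
                                 windows = NULL, sample_step = 1L,
                                 eps = 1e-6, by_condition = TRUE,
                                 keep_plv = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_ch <- d[1]; n_s <- d[2]
  ta <- epochs$time_axis
  if (epochs$fs <= 2 * max(freqs))
    stop("sampling rate must exceed twice the highest analysis frequency")

  step_idx <- function(win) {
    ws <- window_samples(win, ta)
    ws[seq(1L, length(ws), by = sample_step)]
  }
  out_idx <- if (is.null(windows)) {
    seq(1L, n_s, by = sample_step)
  } else {
    sort(unique(c(step_idx(baseline),
                  unlist(lapply(windows, step_idx), use.names = FALSE))))
  }
  bcols <- match(step_idx(baseline), out_idx)
  if (anyNA(bcols)) stop("baseline window not covered by evaluated samples")

  tt <- epochs$trial_table
  conds <- if (by_condition) split(which(tt$valid), tt$side[tt$valid])
           else list(all = which(tt$valid))
  if (any(lengths(conds) < 2))
    stop("each condition needs >= 2 valid trials")

  n_pairs <- n_ch * (n_ch - 1L) / 2L
  rplv_acc <- matrix(0, n_pairs, length(out_idx))
  plv_acc <- if (keep_plv) matrix(0, n_pairs, length(out_idx)) else NULL
  unusable <- logical(n_pairs)
  valid <- NULL

  # one transform over all valid trials; PLV per condition on column blocks
  trials_all <- unlist(conds, use.names = FALSE)
  X <- matrix(aperm(epochs$data[, , trials_all, drop = FALSE], c(2, 1, 3)),
              n_s, n_ch * length(trials_all))
  mc <- morlet_coefs(X, epochs$fs, freqs, n_cycles, out_idx)
  valid <- mc$valid
  offs <- c(0L, cumsum(lengths(conds)))

  for (ci in seq_along(conds)) {
    n_tr <- length(conds[[ci]])
    cols <- (offs[ci] * n_ch + 1L):(offs[ci + 1L] * n_ch)
    band <- matrix(0, n_pairs, length(out_idx))
    for (f in seq_along(freqs)) {
      P <- plv_pairs_cpp(mc$coefs[[f]][, cols, drop = FALSE],
                         n_ch, n_tr, 1e-12)
      if (keep_plv)
        plv_acc <- plv_acc + P / (length(freqs) * length(conds))
      b <- rowMeans(P[, bcols, drop = FALSE])
      bad <- b < eps
      unusable <- unusable | bad
      b[bad] <- NA_real_
      band <- band + (P - b) / b
    }
    rplv_acc <- rplv_acc + band / length(freqs)
  }
  rplv <- rplv_acc / length(conds)
  rplv[unusable, ] <- NA_real_
  if (any(unusable))
    message(sum(unusable), " pair(s) unusable (baseline PLV below ", eps, ")")

  pm <- pair_index(n_ch)
  structure(
    list(
      rplv = rplv,
      plv = plv_acc,
      pairs = pm,
      pair_labels = matrix(epochs$channel_labels[pm], nrow = 2),
      time = ta[out_idx],
      out_idx = out_idx,
      baseline_cols = bcols,
      baseline = baseline,
      freqs = freqs,
      n_cycles = n_cycles,
      valid = valid,
      unusable = unusable,
      channel_labels = epochs$channel_labels,
      subject_id = epochs$subject_id,
      group = epochs$group,
      n_trials = lengths(conds),
      sample_step = sample_step
    ),
    class = "pair_connectivity"
  )
}

#' @export
print.pair_connectivity <- function(x, ...) {
  cat(sprintf("<pair_connectivity> %s (%s): %d pairs x %d samples, %s Hz\n",
              x$subject_id %||% "?", x$group %||% "?",
              nrow(x$rplv), ncol(x$rplv),
              paste(range(x$freqs), collapse = "-")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
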