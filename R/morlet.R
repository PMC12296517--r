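# Complex Morlet wavelet, L2-normalized, truncated at +/- 3 temporal SD.
# sigma_t = n_cycles / (2 pi f); the half-support in samples is
# ceiling(3 sigma_t fs) and defines the edge-invalidity margin.
morlet_kernel <- function(freq, fs, n_cycles) {
  sigma <- n_cycles / (2 * pi * freq)
  h <- as.integer(ceiling(3 * sigma * fs))
  tt <- (-h:h) / fs
  w <- exp(-tt^2 / (2 * sigma^2)) * exp(1i * 2 * pi * freq * tt)
  list(w = w / sqrt(sum(Mod(w)^2)), h = h)
}

# Split sorted sample indices into contiguous-ish runs: a new run starts
# wherever the gap exceeds `gap` samples. Keeps windowed transforms from
# multiplying through the dead stretch between distant analysis windows.
split_runs <- function(idx, gap) {
  brk <- c(0L, which(diff(idx) > gap), length(idx))
  lapply(seq_len(length(brk) - 1L),
         function(i) idx[(brk[i] + 1L):brk[i + 1L]])
}

# Morlet coefficients at selected output samples via banded matrix product.
# X: samples x signals (real). Returns nout x nsignals complex.
morlet_gemm <- function(X, fs, freq, n_cycles, out_idx) {
  k <- morlet_kernel(freq, fs, n_cycles)
  n <- nrow(X)
  acc <- NULL
  for (run in split_runs(out_idx, 2L * k$h)) {
    lo <- max(1L, min(run) - k$h)
    hi <- min(n, max(run) + k$h)
    off <- outer(lo:hi, run, "-")          # input-sample minus output-sample
    inside <- abs(off) <= k$h
    M <- matrix(0 + 0i, nrow(off), ncol(off))
    M[inside] <- Conj(k$w[off[inside] + k$h + 1L])
    Xk <- X[lo:hi, , drop = FALSE]
    co <- crossprod(Re(M), Xk) + 1i * crossprod(Im(M), Xk)
    acc <- if (is.null(acc)) co else rbind(acc, co)
  }
  acc
}

# Morlet coefficients for all frequencies via FFT cross-correlation
# (used when most of the epoch is requested).
morlet_fft <- function(X, fs, freqs, n_cycles, out_idx) {
  n <- nrow(X)
  hmax <- max(vapply(freqs, function(f)
    morlet_kernel(f, fs, n_cycles)$h, integer(1)))
  nfft <- 2^ceiling(log2(n + 2L * hmax + 1L))
  Xp <- rbind(X, matrix(0, nfft - n, ncol(X)))
  FX <- mvfft(Xp)
  lapply(freqs, function(f) {
    k <- morlet_kernel(f, fs, n_cycles)
    kc <- Conj(k$w)                        # correlation kernel K[d], d = -h..h
    # circular-convolution kernel is the flipped K: index u holds K[-u]
    kpad <- complex(length.out = nfft)
    kpad[1:(k$h + 1L)] <- kc[(k$h + 1L):1]                 # u = 0..h -> K[0..-h]
    kpad[(nfft - k$h + 1L):nfft] <- kc[(2L * k$h + 1L):(k$h + 2L)]  # u = -h..-1 -> K[h..1]
    co <- mvfft(FX * fft(kpad), inverse = TRUE)[seq_len(n), , drop = FALSE] / nfft
    co[out_idx, , drop = FALSE]
  })
}

# Dispatcher: coefficients per frequency at `out_idx` (default: all samples),
# plus per-frequency edge-validity of each output sample.
morlet_coefs <- function(X, fs, freqs, n_cycles, out_idx = NULL) {
  n <- nrow(X)
  if (is.null(out_idx)) out_idx <- seq_len(n)
  stopifnot(!is.unsorted(out_idx), out_idx[1] >= 1,
            out_idx[length(out_idx)] <= n)
  hs <- vapply(freqs, function(f) morlet_kernel(f, fs, n_cycles)$h, integer(1))
  if (n <= 2L * max(hs))
    stop("epoch too short for the widest wavelet (", 2L * max(hs) + 1L,
         " samples at ", min(freqs), " Hz)")
  dense <- length(out_idx) > n / 3
  coefs <- if (dense) {
    morlet_fft(X, fs, freqs, n_cycles, out_idx)
  } else {
    lapply(freqs, function(f) morlet_gemm(X, fs, f, n_cycles, out_idx))
  }
  valid <- vapply(hs, function(h) out_idx - h >= 1L & out_idx + h <= n,
                  logical(length(out_idx)))
  valid <- matrix(valid, nrow = length(out_idx))
  list(freqs = freqs, coefs = coefs, valid = valid, out_idx = out_idx)
}

#' Morlet time-frequency phase decomposition
#'
#' Convolves every channel and trial with complex Morlet wavelets (Gaussian-
#' windowed complex exponentials; default 5 cycles) and returns instantaneous
#' phase and amplitude per frequency. Samples closer to an epoch edge than
#' the wavelet half-support, or with amplitude below `floor_amp`, are flagged
#' invalid in `valid` (an all-zero signal yields amplitude 0 and an invalid
#' phase rather than NaN).
#'
#' Note the full tensors are channels x samples x trials x frequencies; for
#' a default-sized subject this is large. The windowed pipeline entry point
#' [subject_connectivity()] avoids materializing them.
#'
#' @param epochs an `epoch_set`.
#' @param freqs analysis frequencies, Hz (theta `4:7` by default; pass
#'   `8:13` for the alpha band).
#' @param n_cycles wavelet cycles (time/frequency resolution trade-off).
#' @param floor_amp amplitude floor below which phase is flagged invalid.
#' @return A `phase_tensor`: list with `phase` (radians in (-pi, pi]),
#'   `amplitude`, `valid` (all channels x samples x trials x frequencies),
#'   `freqs`, `time_axis`, `channel_labels`, `fs`.
#' @examples
#' cfg <- cohort_config(n_per_group = 2, n_trials_per_side = 2,
#'                      epoch_span = c(-3700, -2100))
#' es <- generate_epoch_set("CO01", "CO", cfg, seed = 1)
#' pt <- morlet_phase(es, freqs = 5:6)
#' dim(pt$phase)
#' @export
morlet_phase <- function(epochs, freqs = 4:7, n_cycles = 5,
                         floor_amp = 1e-12) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  n_ch <- d[1]; n_s <- d[2]; n_tr <- d[3]
  if (epochs$fs <= 2 * max(freqs))
    stop("sampling rate must exceed twice the highest analysis frequency")
  X <- matrix(aperm(epochs$data, c(2, 1, 3)), n_s, n_ch * n_tr)
  mc <- morlet_coefs(X, epochs$fs, freqs, n_cycles)
  nf <- length(freqs)
  phase <- array(NA_real_, c(n_ch, n_s, n_tr, nf))
  amplitude <- array(NA_real_, c(n_ch, n_s, n_tr, nf))
  valid <- array(FALSE, c(n_ch, n_s, n_tr, nf))
  for (f in seq_len(nf)) {
    co <- array(mc$coefs[[f]], c(n_s, n_ch, n_tr))
    phase[, , , f] <- aperm(Arg(co), c(2, 1, 3))
    amp <- aperm(Mod(co), c(2, 1, 3))
    amplitude[, , , f] <- amp
    # amplitude floor, and edge validity recycled across channels/trials
    valid[, , , f] <- (amp >= floor_amp) &
      array(rep(mc$valid[, f], each = n_ch), c(n_ch, n_s, n_tr))
  }
  structure(
    list(phase = phase, amplitude = amplitude, valid = valid,
         freqs = freqs, time_axis = epochs$time_axis,
         channel_labels = epochs$channel_labels, fs = epochs$fs,
         n_cycles = n_cycles),
    class = "phase_tensor"
  )
}
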