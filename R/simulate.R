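#' Event-locked coupling profile
#'
#' Von Mises concentration of the pairwise phase coupling as a function of
#' epoch time. Coupling sits at `kappa_base` everywhere except for the
#' `stim_coupling_ms` windows following the warning stimulus (S1) and the
#' imperative stimulus (S2), where `kappa_event` is added. For group
#' `"TS"` the post-S1 gain is reduced by the fraction `group_deficit_s1`;
#' the post-S2 window is deficit-free by construction.
#'
#' @param t time(s) in ms relative to S2; must lie within the epoch span.
#' @param group `"TS"` or `"CO"`.
#' @param config a [cohort_config()].
#' @return Numeric vector of concentrations (same length as `t`).
#' @examples
#' cfg <- cohort_config()
#' coupling_profile(c(-3500, -3100, 100), "TS", cfg)
#' @export
coupling_profile <- function(t, group = c("TS", "CO"), config) {
  group <- match.arg(group)
  stopifnot(inherits(config, "cohort_config"))
  if (any(t < config$epoch_span[1] - 1e-9 | t > config$epoch_span[2] + 1e-9))
    stop(sprintf("t outside the epoch span [%g, %g] ms",
                 config$epoch_span[1], config$epoch_span[2]))
  in_s1 <- t >= config$s1_latency &
    t < config$s1_latency + config$stim_coupling_ms
  in_s2 <- t >= 0 & t < config$stim_coupling_ms
  deficit <- if (group == "TS") config$group_deficit_s1 else 0
  config$kappa_base +
    config$kappa_event * (1 - deficit) * in_s1 +
    config$kappa_event * in_s2
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler, vectorized; `kappa = 0` falls back to the
#' circular uniform. Mean direction is 0.
#'
#' @param n number of draws.
#' @param kappa concentration (>= 0).
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, kappa) {
  n <- as.integer(n)
  if (n == 0) return(numeric(0))
  stopifnot(kappa >= 0)
  if (kappa < 1e-8) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    m <- max(16L, ceiling((n - filled) / 0.6))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    f <- f[ok]; u3 <- u3[ok]
    k <- min(length(f), n - filled)
    if (k > 0) {
      th <- sign(u3[seq_len(k)] - 0.5) *
        acos(pmin(pmax(f[seq_len(k)], -1), 1))
      out[filled + seq_len(k)] <- th
      filled <- filled + k
    }
  }
  out
}

# Spectrally shaped Gaussian noise with power density ~ 1/f^exponent.
# Returns an n x m matrix with unit expected SD per sample (analytic
# scaling). Columns are independent. Synthesized in the frequency domain:
# hermitian-symmetric complex Gaussian spectrum, one inverse FFT. The bulk
# normal draws come from a dedicated C++ stream whose seed is drawn from
# R's RNG, so everything still derives from the root seed.
noise_1f <- function(n, m, exponent, fs) {
  nfft <- 2^ceiling(log2(max(n, 16)))
  nh <- nfft / 2
  amp <- ((1:nh) * fs / nfft)^(-exponent / 2)
  g <- gauss_mat_cpp(nh, 2L * m, sample.int(.Machine$integer.max, 1L))
  spec <- matrix(0 + 0i, nfft, m)
  spec[2:(nh + 1), ] <- complex(real = g[, seq_len(m)],
                                imaginary = g[, m + seq_len(m)]) * amp
  spec[nh + 1, ] <- Re(spec[nh + 1, ])          # Nyquist bin must be real
  spec[seq(nfft, nh + 2), ] <- Conj(spec[2:nh, ])
  x <- Re(mvfft(spec, inverse = TRUE))[seq_len(n), , drop = FALSE]
  # R's inverse mvfft is unnormalized; per-sample variance of x is
  # 4 * sum_{k<nh} amp_k^2 + amp_nh^2 (hermitian pairs + real Nyquist bin)
  sd_theory <- sqrt(4 * sum(amp[seq_len(nh - 1)]^2) + amp[nh]^2)
  x / sd_theory
}

# Piecewise-constant coupling segmentation of the epoch. Boundaries fall at
# stimulus-window edges; kappa per segment includes the subject's lognormal
# event-gain scales and the TS post-S1 deficit.
coupling_segments <- function(config, group, scale_s1, scale_s2, time_axis) {
  span <- config$epoch_span
  ev <- c(config$s1_latency, config$s1_latency + config$stim_coupling_ms,
          0, config$stim_coupling_ms)
  b <- sort(unique(ev[ev > span[1] & ev < span[2]]))
  id <- findInterval(time_axis, c(span[1] - 1e-9, b))
  edges <- c(span[1], b, span[2])
  mid <- (edges[-length(edges)] + edges[-1]) / 2
  in_s1 <- mid >= config$s1_latency &
    mid < config$s1_latency + config$stim_coupling_ms
  in_s2 <- mid >= 0 & mid < config$stim_coupling_ms
  deficit <- if (group == "TS") config$group_deficit_s1 else 0
  kappa <- config$kappa_base +
    config$kappa_event * (1 - deficit) * scale_s1 * in_s1 +
    config$kappa_event * scale_s2 * in_s2
  list(id = id, kappa = kappa, edges = edges, in_s1 = in_s1, in_s2 = in_s2)
}

# Per-trial behavioral simulation. RTs follow
#   rt = rt_intercept + rt_slope * scale_s2 + N(0, rt_sigma),
# anticipatory presses (between S1 and S2) have no S2-locked RT, and a
# non-anticipatory response uses the wrong side with probability error_rate.
simulate_behavior <- function(subject_id, sides, scale_s2, config) {
  n <- length(sides)
  anticipatory <- runif(n) < config$anticipatory_rate
  correct <- !anticipatory & (runif(n) >= config$error_rate)
  rt <- config$rt_intercept + config$rt_slope * scale_s2 +
    rnorm(n, 0, config$rt_sigma)
  rt[anticipatory] <- NA_real_
  data.frame(
    subject_id = subject_id,
    trial = seq_len(n),
    side = sides,
    rt_ms = rt,
    anticipatory = anticipatory,
    correct = correct,
    stringsAsFactors = FALSE
  )
}

# One subject: epochs + behavioral record, all randomness from `seed`.
generate_subject <- function(subject_id, group, config, seed) {
  set.seed(seed)
  chans <- roi_channels(config$roi_map)
  n_ch <- length(chans)
  fs <- config$fs
  ta <- seq(config$epoch_span[1], config$epoch_span[2], by = 1000 / fs)
  n_s <- length(ta)
  n_tr <- 2L * config$n_trials_per_side

  # subject-level lognormal scaling of the event coupling gain
  scale_s1 <- exp(rnorm(1, 0, config$subject_sdlog))
  scale_s2 <- exp(rnorm(1, 0, config$subject_sdlog))

  sides <- sample(rep(c("left", "right"), config$n_trials_per_side))
  behavior <- simulate_behavior(subject_id, sides, scale_s2, config)

  seg <- coupling_segments(config, group, scale_s1, scale_s2, ta)
  n_seg <- length(seg$kappa)
  n_area <- length(config$roi_map)
  area_of <- rep(seq_along(config$roi_map), lengths(config$roi_map))

  # trial-global theta oscillator: frequency redrawn per trial in 4-7 Hz
  f_tr <- runif(n_tr, 4, 7)
  phi0 <- runif(n_tr, -pi, pi)
  G <- outer((ta - ta[1]) / 1000, 2 * pi * f_tr) +
    matrix(phi0, n_s, n_tr, byrow = TRUE)              # n_s x n_tr

  # hierarchical von Mises phase coupling: area offsets around the global
  # oscillator, electrode jitter around the area, both with segmentwise
  # concentration from the coupling profile
  alpha <- array(0, c(n_seg, n_area, n_tr))
  theta <- array(0, c(n_seg, n_ch, n_tr))
  for (s in seq_len(n_seg)) {
    alpha[s, , ] <- rvonmises(n_area * n_tr, seg$kappa[s])
    theta[s, , ] <- rvonmises(n_ch * n_tr, seg$kappa[s])
  }

  noise <- noise_1f(n_s, n_ch * n_tr, config$noise_exponent, fs)
  # snr is an RMS amplitude ratio; the unit oscillation has RMS 1/sqrt(2)
  x <- assemble_epochs_cpp(G, alpha, theta, seg$id, area_of, noise,
                           (1 / sqrt(2)) / config$snr)

  # a trial enters the EEG analysis when the response was correct and
  # landed within 1.5 s of S2
  valid <- behavior$correct & !is.na(behavior$rt_ms) & behavior$rt_ms < 1500

  epochs <- structure(
    list(
      subject_id = subject_id,
      group = group,
      data = x,
      time_axis = ta,
      channel_labels = chans,
      fs = fs,
      trial_table = data.frame(trial = seq_len(n_tr), side = sides,
                               valid = valid, stringsAsFactors = FALSE),
      sim_truth = list(seed = seed, scale_s1 = scale_s1, scale_s2 = scale_s2,
                       kappa_segments = seg$kappa, segment_edges = seg$edges)
    ),
    class = "epoch_set"
  )
  list(epochs = epochs, behavior = behavior)
}

#' Generate one subject's epoched recording
#'
#' Simulates epoched multichannel oscillatory data with event-locked phase
#' coupling. Each trial carries one latent theta oscillator (frequency
#' uniform in 4-7 Hz); each ROI area receives a von Mises phase offset
#' around it, and each electrode a further von Mises jitter around its
#' area, with segmentwise concentration following [coupling_profile()]
#' (so both within- and between-area synchrony are event-modulated).
#' Spectrally shaped 1/f Gaussian noise is added at the configured SNR.
#' Deterministic given `seed`.
#'
#' @param subject_id character id.
#' @param group `"TS"` or `"CO"`.
#' @param config a [cohort_config()].
#' @param seed integer seed for this subject.
#' @return An `epoch_set`: channels x samples x trials data array plus time
#'   axis (ms relative to S2), channel labels, sampling rate, trial table
#'   (side, validity) and the injected ground truth (`sim_truth`).
#' @examples
#' cfg <- cohort_config(n_per_group = 2, n_trials_per_side = 3,
#'                      epoch_span = c(-3700, -2100))
#' es <- generate_epoch_set("TS01", "TS", cfg, seed = 7)
#' dim(es$data)
#' @export
generate_epoch_set <- function(subject_id, group = c("TS", "CO"), config,
                               seed = config$seed) {
  group <- match.arg(group)
  stopifnot(inherits(config, "cohort_config"))
  generate_subject(subject_id, group, config, seed)$epochs
}

#' Generate a synthetic two-group cohort
#'
#' `n_per_group` subjects per group ("TS", "CO"), each simulated by
#' [generate_epoch_set()] with a per-subject seed derived from the root
#' `config$seed`, plus matched behavioral records.
#'
#' @param config a [cohort_config()].
#' @return A `plv_cohort`: list with `subjects` (each a list of `epochs`
#'   and `behavior`) and the `config`.
#' @examples
#' cfg <- cohort_config(n_per_group = 2, n_trials_per_side = 3,
#'                      epoch_span = c(-3700, -2100))
#' coh <- generate_cohort(cfg)
#' length(coh$subjects)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- 2L * config$n_per_group
  set.seed(config$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  groups <- rep(c("TS", "CO"), each = config$n_per_group)
  ids <- c(sprintf("TS%02d", seq_len(config$n_per_group)),
           sprintf("CO%02d", seq_len(config$n_per_group)))
  subjects <- vector("list", n)
  for (i in seq_len(n))
    subjects[[i]] <- generate_subject(ids[i], groups[i], config, subj_seeds[i])
  names(subjects) <- ids
  structure(list(subjects = subjects, config = config), class = "plv_cohort")
}

#' Combined behavioral table of a cohort
#' @param cohort a `plv_cohort`.
#' @return One data.frame of all per-trial behavioral records, with a
#'   `group` column.
#' @export
behavior_table <- function(cohort) {
  stopifnot(inherits(cohort, "plv_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) {
    b <- s$behavior
    b$group <- s$epochs$group
    b
  }))
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s (%s): %d channels x %d samples x %d trials @ %g Hz\n",
              x$subject_id, x$group, d[1], d[2], d[3], x$fs))
  cat(sprintf("  time [%g, %g] ms re S2; %d/%d valid trials\n",
              x$time_axis[1], x$time_axis[length(x$time_axis)],
              sum(x$trial_table$valid), nrow(x$trial_table)))
  invisible(x)
}

#' @export
print.plv_cohort <- function(x, ...) {
  grp <- vapply(x$subjects, function(s) s$epochs$group, character(1))
  cat(sprintf("<plv_cohort> %d subjects (TS: %d, CO: %d)\n",
              length(x$subjects), sum(grp == "TS"), sum(grp == "CO")))
  invisible(x)
}
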