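#' Configuration for a synthetic two-group cohort
#'
#' Bundles every tunable of the synthetic-cohort generator. Defaults emulate
#' a pre-cued reaction-time (CNV) study: 200 Hz epochs from -3.7 s to +3.0 s
#' around the imperative stimulus (S2), warning stimulus (S1) at -3.2 s,
#' 50 trials per response side, 20 subjects per group, 31 ROI electrodes in
#' six areas, and theta-range oscillations whose pairwise phase coupling
#' tightens for 500 ms after each stimulus. The patient group ("TS") carries
#' a fractional reduction of the post-S1 coupling gain; reaction times are
#' linearly tied to each subject's post-S2 coupling scale so that network
#' efficiency predicts behavior by construction.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_trials_per_side trials per response side (left/right).
#' @param fs sampling rate, Hz.
#' @param epoch_span epoch limits in ms relative to S2, `c(start, end)`.
#' @param s1_latency S1 onset in ms relative to S2 (negative).
#' @param stim_coupling_ms duration of elevated coupling after each
#'   stimulus onset, ms.
#' @param roi_map area -> electrode map; see [default_roi_map()].
#' @param kappa_base baseline von Mises concentration of the phase coupling.
#' @param kappa_event added concentration inside post-stimulus windows.
#' @param group_deficit_s1 fractional reduction (0..1) of `kappa_event` in
#'   the post-S1 window for group "TS".
#' @param noise_exponent spectral slope of the 1/f^a background noise.
#' @param snr oscillation-to-noise RMS amplitude ratio.
#' @param subject_sdlog log-SD of the per-subject lognormal scaling of the
#'   event coupling gain (drawn independently for the post-S1 and post-S2
#'   windows; the post-S2 scale also drives reaction times).
#' @param rt_intercept,rt_slope,rt_sigma reaction-time model, ms: per trial
#'   `rt = rt_intercept + rt_slope * scale_s2 + N(0, rt_sigma)`.
#' @param anticipatory_rate probability of a premature press between S1
#'   and S2 on any trial.
#' @param error_rate probability that a non-anticipatory response uses the
#'   wrong side.
#' @param seed root seed; all generator randomness derives from it.
#' @return List of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_per_group = 2, n_trials_per_side = 5)
#' cfg$fs
#' @export
cohort_config <- function(n_per_group = 20,
                          n_trials_per_side = 50,
                          fs = 200,
                          epoch_span = c(-3700, 3000),
                          s1_latency = -3200,
                          stim_coupling_ms = 500,
                          roi_map = default_roi_map(),
                          kappa_base = 2,
                          kappa_event = 6,
                          group_deficit_s1 = 0.5,
                          noise_exponent = 1,
                          snr = 1,
                          subject_sdlog = 0.35,
                          rt_intercept = 430,
                          rt_slope = -100,
                          rt_sigma = 50,
                          anticipatory_rate = 0.07,
                          error_rate = 0.05,
                          seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_trials_per_side = as.integer(n_trials_per_side),
    fs = fs,
    epoch_span = as.numeric(epoch_span),
    s1_latency = s1_latency,
    stim_coupling_ms = stim_coupling_ms,
    roi_map = validate_roi_map(roi_map),
    kappa_base = kappa_base,
    kappa_event = kappa_event,
    group_deficit_s1 = group_deficit_s1,
    noise_exponent = noise_exponent,
    snr = snr,
    subject_sdlog = subject_sdlog,
    rt_intercept = rt_intercept,
    rt_slope = rt_slope,
    rt_sigma = rt_sigma,
    anticipatory_rate = anticipatory_rate,
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    "n_per_group must be >= 2" = cfg$n_per_group >= 2,
    "n_trials_per_side must be >= 1" = cfg$n_trials_per_side >= 1,
    "fs must exceed twice the highest theta analysis frequency (14 Hz)" =
      cfg$fs > 14,
    "epoch_span must be an increasing pair" =
      length(cfg$epoch_span) == 2 && diff(cfg$epoch_span) > 0,
    "S1 must fall inside the epoch" =
      cfg$s1_latency > cfg$epoch_span[1] && cfg$s1_latency < cfg$epoch_span[2],
    "epoch must cover a pre-S1 baseline" =
      cfg$epoch_span[1] <= cfg$s1_latency - 100,
    "stim_coupling_ms must be positive" = cfg$stim_coupling_ms > 0,
    "kappa values must be >= 0" = cfg$kappa_base >= 0 && cfg$kappa_event >= 0,
    "group_deficit_s1 must lie in [0, 1]" =
      cfg$group_deficit_s1 >= 0 && cfg$group_deficit_s1 <= 1,
    "snr must be positive" = cfg$snr > 0,
    "rt_sigma must be >= 0" = cfg$rt_sigma >= 0,
    "anticipatory_rate must lie in [0, 1)" =
      cfg$anticipatory_rate >= 0 && cfg$anticipatory_rate < 1,
    "error_rate must lie in [0, 1)" =
      cfg$error_rate >= 0 && cfg$error_rate < 1
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects/group, %d trials/side, fs = %g Hz\n",
              x$n_per_group, x$n_trials_per_side, x$fs))
  cat(sprintf("  epoch [%g, %g] ms re S2, S1 at %g ms\n",
              x$epoch_span[1], x$epoch_span[2], x$s1_latency))
  cat(sprintf("  kappa: base %g, event +%g, TS post-S1 deficit %g\n",
              x$kappa_base, x$kappa_event, x$group_deficit_s1))
  cat(sprintf("  noise 1/f^%g at snr %g; RT = %g %+g*scale (sd %g) ms\n",
              x$noise_exponent, x$snr, x$rt_intercept, x$rt_slope, x$rt_sigma))
  invisible(x)
}

# ms -> sample index (1-based) on a uniform time axis; floor convention so
# that half-open windows [a, b) map to disjoint, exhaustive sample sets.
ms_to_sample <- function(t_ms, time_axis, fs) {
  1L + as.integer(floor((t_ms - time_axis[1]) * fs / 1000 + 1e-9))
}

# Sample indices of a half-open window [w1, w2) ms.
window_samples <- function(window, time_axis) {
  idx <- which(time_axis >= window[1] - 1e-9 & time_axis < window[2] - 1e-9)
  if (length(idx) == 0)
    stop(sprintf("window [%g, %g) ms contains no samples", window[1], window[2]))
  idx
}
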