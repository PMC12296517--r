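test_that("coupling profile follows the event windows and group deficit", {
  cfg <- cohort_config(kappa_base = 1, kappa_event = 4,
                       group_deficit_s1 = 0.5)
  # outside all stimulus windows: baseline concentration for both groups
  expect_equal(coupling_profile(-3500, "TS", cfg), 1)
  expect_equal(coupling_profile(-3500, "CO", cfg), 1)
  expect_equal(coupling_profile(1200, "CO", cfg), 1)
  # post-S2 window is deficit-free for both groups
  expect_equal(coupling_profile(100, "TS", cfg), 5)
  expect_equal(coupling_profile(100, "CO", cfg), 5)
  # post-S1 window carries the TS deficit
  expect_equal(coupling_profile(-3000, "CO", cfg), 5)
  expect_equal(coupling_profile(-3000, "TS", cfg), 3)
  # half-open boundaries
  expect_equal(coupling_profile(c(-3200, -2700, 0, 500), "CO", cfg),
               c(5, 1, 5, 1))
  # outside the epoch span -> error
  expect_error(coupling_profile(-4000, "TS", cfg), "epoch span")
  expect_error(coupling_profile(3500, "TS", cfg), "epoch span")
})

test_that("cohort configuration enforces its invariants", {
  expect_error(cohort_config(n_per_group = 1), "n_per_group")
  expect_error(cohort_config(fs = 10), "twice the highest")
  expect_error(cohort_config(group_deficit_s1 = 1.5), "0, 1")
  expect_error(cohort_config(kappa_base = -1), "kappa")
  expect_error(cohort_config(epoch_span = c(-3250, 3000)), "baseline")
})

test_that("epoch sets have the contracted geometry", {
  cfg <- tiny_config()
  es <- generate_epoch_set("TS01", "TS", cfg, seed = 11)
  d <- dim(es$data)
  expect_identical(d[1], 31L)                    # ROI electrodes
  expect_identical(d[3], 2L * cfg$n_trials_per_side)
  # samples == round(span / 1000 * fs) + 1
  expect_identical(
    d[2], as.integer(round(diff(cfg$epoch_span) / 1000 * cfg$fs)) + 1L)
  # uniform, strictly increasing time axis at 1000 / fs ms
  expect_equal(unique(round(diff(es$time_axis), 9)), 1000 / cfg$fs)
  expect_true(all(roi_channels(cfg$roi_map) %in% es$channel_labels))
  # baseline window lies inside the epoch
  expect_true(es$time_axis[1] <= -3700 && max(es$time_axis) >= -3200)
})

test_that("generation is deterministic given the seed", {
  cfg <- tiny_config()
  a <- generate_epoch_set("S", "TS", cfg, seed = 99)
  b <- generate_epoch_set("S", "TS", cfg, seed = 99)
  expect_identical(a, b)
  c <- generate_epoch_set("S", "TS", cfg, seed = 100)
  expect_false(identical(a$data, c$data))
  # cohort-level determinism (serialized byte-level)
  co1 <- generate_cohort(tiny_config(seed = 5))
  co2 <- generate_cohort(tiny_config(seed = 5))
  expect_identical(serialize(co1, NULL), serialize(co2, NULL))
})

test_that("cohorts have the configured shape and balanced groups", {
  cfg <- tiny_config(n_per_group = 3)
  coh <- generate_cohort(cfg)
  expect_length(coh$subjects, 6)
  grp <- vapply(coh$subjects, function(s) s$epochs$group, character(1))
  expect_equal(unname(table(grp)["TS"]), 3L)
  beh <- behavior_table(coh)
  expect_equal(nrow(beh), 6 * 2 * cfg$n_trials_per_side)
  expect_true(all(beh$rt_ms[!beh$anticipatory] > 0, na.rm = TRUE))
  expect_true(all(is.na(beh$rt_ms[beh$anticipatory])))
  # sides balanced within subject
  s1 <- coh$subjects[[1]]$epochs$trial_table
  expect_equal(sum(s1$side == "left"), cfg$n_trials_per_side)
})

test_that("von Mises sampler matches the Bessel resultant", {
  set.seed(42)
  for (k in c(0, 1, 4)) {
    th <- rvonmises(4e4, k)
    expect_true(all(th > -pi & th <= pi + 1e-12))
    r_emp <- Mod(mean(exp(1i * th)))
    r_th <- if (k == 0) 0 else besselI(k, 1) / besselI(k, 0)
    expect_lt(abs(r_emp - r_th), 0.02)
    # symmetric around 0
    expect_lt(abs(Arg(mean(exp(1i * rvonmises(4e4, max(k, 0.5)))))), 0.05)
  }
})

test_that("1/f noise has the configured spectral slope", {
  set.seed(7)
  x <- plvnet:::noise_1f(2048, 50, 1, 200)
  expect_lt(abs(sd(x) - 1), 0.05)
  # periodogram log-log slope ~ -exponent
  sp <- Mod(mvfft(x))^2
  f <- (1:512) * 200 / 2048
  m <- rowMeans(sp[2:513, , drop = FALSE])
  slope <- coef(lm(log(m) ~ log(f)))[2]
  expect_lt(abs(slope - (-1)), 0.15)
})

test_that("post-stimulus PLV exceeds baseline for within-area pairs when
           coupling is strong and noise is off", {
  cfg <- cue_config(kappa_base = 0.5, kappa_event = 8, snr = 1e9,
                    group_deficit_s1 = 0)
  es <- generate_epoch_set("CO01", "CO", cfg, seed = 21)
  expect_gte(sum(es$trial_table$valid), 50)
  pc <- subject_connectivity(es, windows = list(S1 = c(-3200, -2700)),
                             sample_step = 2L, keep_plv = TRUE)
  pm <- plvnet:::pair_map(cfg$roi_map, es$channel_labels)
  within <- pm$rows[pm$areas[1, ] == pm$areas[2, ]]
  s1 <- which(pc$time >= -3200 & pc$time < -2700)
  post <- rowMeans(pc$plv[within, s1])
  base <- rowMeans(pc$plv[within, pc$baseline_cols])
  expect_true(all(post > base))
})

test_that("measured post-S1 rPLV increases monotonically in kappa_event", {
  rplv_at <- function(ke) {
    cfg <- cue_config(kappa_event = ke, group_deficit_s1 = 0, seed = 33)
    es <- generate_epoch_set("CO01", "CO", cfg, seed = 33)
    pc <- subject_connectivity(es, windows = list(S1 = c(-3200, -2700)),
                               sample_step = 5L)
    mean_network_rplv(pc, c(-3200, -2700))
  }
  ks <- c(0, 1, 2, 4, 8)
  vals <- vapply(ks, rplv_at, numeric(1))
  expect_gt(cor(ks, vals, method = "spearman"), 0.9)
  # the three-point sweep of the profile example is strictly increasing
  expect_true(all(diff(vals[c(1, 3, 5)]) > 0))
})

test_that("reaction times inherit the injected coupling-scale link", {
  cfg <- tiny_config(n_per_group = 10, rt_slope = 0, rt_sigma = 1)
  coh <- generate_cohort(cfg)
  beh <- behavioral_summary(behavior_table(coh))
  # slope 0: all subject means near the intercept
  expect_lt(diff(range(beh$rt_mean)), 5)
  cfg2 <- tiny_config(n_per_group = 10, rt_slope = -100, rt_sigma = 1)
  coh2 <- generate_cohort(cfg2)
  truth <- vapply(coh2$subjects, function(s) s$epochs$sim_truth$scale_s2,
                  numeric(1))
  beh2 <- behavioral_summary(behavior_table(coh2))
  truth <- truth[beh2$subject_id]        # align to the summary's order
  fit <- lm(beh2$rt_mean ~ truth)
  ci <- confint(fit)[2, ]
  expect_lt(coef(fit)[2], 0)
  expect_true(ci[1] <= -100 && -100 <= ci[2])
})
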