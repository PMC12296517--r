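test_that("PLV is 1 for a constant phase offset and 0 for antipodal pairs", {
  set.seed(1)
  ph <- matrix(runif(10 * 6, -pi, pi), 10, 6)
  expect_equal(plv_timecourse(ph, ph + pi / 3), rep(1, 10))
  # phase differences alternating 0, pi across an even trial count
  d <- matrix(rep(c(0, pi), 3), 10, 6, byrow = TRUE)
  expect_equal(plv_timecourse(ph, ph + d), rep(0, 10))
})

test_that("PLV matches the brute-force oracle and is symmetric and bounded", {
  set.seed(2)
  for (n_tr in 2:4) {
    pi_ <- matrix(runif(20 * n_tr, -pi, pi), 20, n_tr)
    pj_ <- matrix(runif(20 * n_tr, -pi, pi), 20, n_tr)
    v <- plv_timecourse(pi_, pj_)
    expect_equal(v, plv_bruteforce(pi_, pj_), tolerance = 1e-12)
    expect_identical(v, plv_timecourse(pj_, pi_))
    expect_true(all(v >= 0 & v <= 1 + 1e-12))
  }
  expect_error(plv_timecourse(matrix(0, 3, 1), matrix(0, 3, 1)), "2 trials")
  expect_error(plv_timecourse(matrix(0, 3, 4), matrix(0, 4, 4)), "identical")
})

test_that("compiled pair kernel agrees with the plain-R reference", {
  set.seed(3)
  co <- matrix(complex(real = rnorm(15 * 20), imaginary = rnorm(15 * 20)),
               15, 20)                          # 5 channels x 4 trials
  a <- plvnet:::plv_pairs_cpp(co, 5, 4, 1e-12)
  b <- plvnet:::plv_pairs_ref(co, 5, 4)
  expect_equal(a, b, tolerance = 1e-12)
  # degenerate (zero) coefficients contribute zero phasors, not NaN
  co[, 3] <- 0 + 0i
  expect_false(any(is.nan(plvnet:::plv_pairs_cpp(co, 5, 4, 1e-12))))
})

test_that("uniform phase differences give the Rayleigh resultant mean", {
  set.seed(4)
  n <- 100
  plv <- replicate(1000, plv_timecourse(matrix(runif(n, -pi, pi), 1, n),
                                        matrix(0, 1, n)))
  expect_lt(abs(mean(plv) - sqrt(pi) / (2 * sqrt(n))), 0.02)
})

test_that("rPLV normalization identities hold", {
  ta <- seq(-3700, by = 5, length.out = 300)
  base <- c(-3700, -3200)
  # PLV constant at its baseline mean -> rPLV identically 0
  plv <- matrix(0.4, 300, 4)
  expect_equal(unname(relative_plv(plv, ta, base))[1:300], rep(0, 300))
  # PLV = 2 * baseline at one sample -> rPLV = 1 there
  plv[150, ] <- 0.8
  rp <- relative_plv(plv, ta, base)
  expect_equal(rp[[150]], 1)
  # arbitrary input: baseline time-mean of rPLV is 0 to float tolerance
  set.seed(5)
  plv2 <- matrix(runif(300 * 4, 0.05, 0.9), 300, 4)
  rp2 <- relative_plv(plv2, ta, base)
  bidx <- which(ta >= -3700 & ta < -3200)
  expect_lt(abs(mean(rp2[bidx])), 1e-12)
})

test_that("a vanishing baseline flags the pair unusable instead of dividing", {
  ta <- seq(-3700, by = 5, length.out = 200)
  plv <- matrix(1e-9, 200, 2)
  expect_warning(rp <- relative_plv(plv, ta, c(-3700, -3200)), "unusable")
  expect_true(all(is.na(rp)))
  expect_true(attr(rp, "unusable"))
})

test_that("subject connectivity is reproducible, bounded and baseline-true", {
  cfg <- tiny_config(n_trials_per_side = 6)
  es <- generate_epoch_set("TS01", "TS", cfg, seed = 14)
  pc <- subject_connectivity(es, windows = list(S1 = c(-3200, -2700)),
                             keep_plv = TRUE)
  expect_identical(dim(pc$rplv), c(465L, length(pc$time)))
  expect_true(all(pc$plv >= 0 & pc$plv <= 1 + 1e-12))
  # per-pair baseline mean of band rPLV is 0 (per condition and frequency,
  # hence for their average too)
  expect_lt(max(abs(rowMeans(pc$rplv[, pc$baseline_cols]))), 1e-10)
  pc2 <- subject_connectivity(es, windows = list(S1 = c(-3200, -2700)),
                              keep_plv = TRUE)
  expect_identical(pc$rplv, pc2$rplv)
})

test_that("electrodes sharing one oscillator phase give PLV 1 at all valid
           samples", {
  # two channels carrying the identical noise-free signal
  fs <- 200
  ta <- seq(-3700, -2100, by = 1000 / fs)
  n_tr <- 4
  data <- array(0, c(2, length(ta), n_tr))
  for (n in seq_len(n_tr)) {
    f <- 4 + n / 2
    x <- cos(2 * pi * f * ta / 1000 + n)
    data[1, , n] <- x
    data[2, , n] <- x
  }
  es <- structure(
    list(subject_id = "twin", group = "CO", data = data, time_axis = ta,
         channel_labels = c("a", "b"), fs = fs,
         trial_table = data.frame(trial = seq_len(n_tr), side = "left",
                                  valid = TRUE)),
    class = "epoch_set")
  pc <- subject_connectivity(es, windows = list(S1 = c(-3200, -2700)),
                             keep_plv = TRUE, by_condition = FALSE)
  expect_true(all(abs(pc$plv - 1) < 1e-9))
})

test_that("the alpha band runs through the same code path by configuration", {
  cfg <- tiny_config(n_trials_per_side = 6)
  es <- generate_epoch_set("CO01", "CO", cfg, seed = 15)
  pc <- subject_connectivity(es, freqs = 8:13,
                             windows = list(S1 = c(-3200, -2700)),
                             keep_plv = TRUE)
  expect_identical(pc$freqs, 8:13)
  expect_true(all(pc$plv >= 0 & pc$plv <= 1 + 1e-12))
  expect_lt(max(abs(rowMeans(pc$rplv[, pc$baseline_cols]))), 1e-10)
})
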