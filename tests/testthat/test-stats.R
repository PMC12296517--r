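test_that("pointwise increase map behaves per the t-test oracle", {
  set.seed(27)
  # consistent positive rPLV across 20 subjects -> strong evidence
  x <- matrix(0.3 + rnorm(20 * 5, sd = 0.02), 20, 5)
  map <- pointwise_increase_map(x)
  expect_true(all(map > 3))
  # direct oracle at one cell
  tt <- t.test(x[, 3], mu = 0, alternative = "greater")
  expect_equal(unname(map[1, 3]), -log10(tt$p.value), tolerance = 1e-10)
  # values symmetric about 0 -> mean map value near -log10(0.5)
  y <- array(rnorm(20 * 4 * 200), c(20, 4, 200))
  mp <- pointwise_increase_map(y)
  expect_lt(abs(mean(mp) - (-log10(0.5))), 0.15)
  # all-zero input hits the degenerate rule: p = 1, map value 0
  z <- matrix(0, 10, 3)
  expect_true(all(pointwise_increase_map(z) == 0))
  expect_error(pointwise_increase_map(matrix(0, 2, 3)), ">= 3 subjects")
})

test_that("Mann-Whitney matches exact enumeration for small tie-free
           samples", {
  gc <- mann_whitney_compare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$u, 0)
  expect_equal(gc$p, 0.1)
  set.seed(28)
  for (r in 1:12) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(100, n1); y <- sample(200:300, n2) / 7
    gc <- mann_whitney_compare(x, y)
    expect_equal(gc$p, mwu_enumeration_p(x, y), tolerance = 1e-12)
    expect_true(gc$u >= 0 && gc$u <= n1 * n2)
  }
})

test_that("identical groups give the null U and the Z-to-r convention holds", {
  x <- c(1, 2, 3, 4)
  gc <- mann_whitney_compare(x, x)
  expect_equal(gc$u, length(x)^2 / 2)
  expect_equal(gc$p, 1)
  # r = |Z| / sqrt(N): the published Z = -2.76 at n = 20 + 20 pairs with
  # r = 0.44
  expect_equal(2.76 / sqrt(40), 0.436, tolerance = 0.002)
  set.seed(29)
  a <- rnorm(20); b <- rnorm(20) + 1
  gc2 <- mann_whitney_compare(a, b)
  expect_equal(gc2$r, abs(gc2$z) / sqrt(40), tolerance = 1e-12)
  expect_error(mann_whitney_compare(numeric(0), a), "non-empty")
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(30)
  p <- runif(50)
  expect_equal(fdr_adjust(p), bh_stepup(p), tolerance = 1e-12)
  # never decreases any p; rejects a superset of Bonferroni at q = 0.05
  expect_true(all(fdr_adjust(p) >= p))
  expect_true(all(which(p.adjust(p, "bonferroni") < 0.05) %in%
                  which(fdr_adjust(p) < 0.05)))
  expect_error(fdr_adjust(c(0.5, 0)), "p > 0")
})

test_that("behavioral summaries apply the RT filters and count errors", {
  b <- data.frame(
    subject_id = "s1",
    trial = 1:6,
    side = c("left", "left", "right", "right", "left", "right"),
    rt_ms = c(100, 300, 1600, 400, NA, 310),
    anticipatory = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    correct = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  s <- behavioral_summary(b)
  # RT 100 (too fast), RT 1600 (too slow), anticipatory and incorrect
  # trials are excluded from the RT pool
  expect_identical(s$n_valid_rt, 2L)
  expect_equal(s$rt_median_left, 300)
  expect_equal(s$rt_median_right, 400)
  expect_equal(s$accuracy, 100 * 4 / 6)
  expect_identical(s$anticipatory_n, 1L)
  expect_true(s$valid)
  # no valid trials -> flagged invalid
  b2 <- b; b2$rt_ms <- 2000
  expect_false(behavioral_summary(b2)$valid)
})

test_that("efficiency-RT regression reproduces its oracles", {
  e <- seq(0.2, 0.8, length.out = 20)
  # exact linear relation -> R^2 = 1
  fit <- suppressWarnings(efficiency_rt_regression(e, 500 - 200 * e))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, -200, tolerance = 1e-9)
  # independent outcome -> E[R^2] = 1 / (n - 1)
  set.seed(31)
  r2 <- replicate(400, efficiency_rt_regression(e, rnorm(20))$r_squared)
  expect_lt(abs(mean(r2) - 1 / 19), 0.015)
  expect_error(efficiency_rt_regression(rep(0.5, 10), rnorm(10)),
               "zero-variance")
  expect_error(efficiency_rt_regression(e[1:2], rnorm(2)), ">= 3")
})

test_that("chi-square worked example: identical proportions give 0", {
  ct <- group_chisq(16, 20, 16, 20)
  expect_equal(ct$statistic, 0)
  expect_equal(ct$p, 1)
  expect_equal(ct$df, 1)
  ct2 <- group_chisq(18, 20, 10, 20)
  expect_gt(ct2$statistic, 0)
})

test_that("the statistical layer is pure (no hidden RNG)", {
  set.seed(32); x <- rnorm(15); y <- rnorm(12) + 0.5
  seed_before <- .Random.seed
  a <- mann_whitney_compare(x, y)
  b <- fdr_adjust(c(0.2, 0.01))
  d <- suppressWarnings(efficiency_rt_regression(seq_len(10), (1:10) * 2 + 3))
  expect_identical(seed_before, .Random.seed)
  expect_identical(a, mann_whitney_compare(x, y))
})
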