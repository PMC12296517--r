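test_that("Euclidean distance time course follows the norm identities", {
  set.seed(10)
  a <- array(rnorm(5 * 21 * 3), c(5, 21, 3))
  # identical group means -> d = 0 everywhere
  d0 <- euclidean_timecourse(a, a)
  expect_equal(d0$d, rep(0, 3))
  # single-coordinate shift of 0.3
  b <- a
  b[, 7, ] <- b[, 7, ] + 0.3
  expect_equal(euclidean_timecourse(a, b)$d, rep(0.3, 3), tolerance = 1e-12)
  # all 21 coordinates shifted by 0.1 -> sqrt(21) * 0.1
  b2 <- a + 0.1
  expect_equal(euclidean_timecourse(a, b2)$d,
               rep(sqrt(21) * 0.1, 3), tolerance = 1e-12)
})

test_that("distance is invariant to a common feature permutation and the
           within-group variance matches a direct computation", {
  set.seed(11)
  a <- array(rnorm(6 * 21 * 4), c(6, 21, 4))
  b <- array(rnorm(7 * 21 * 4), c(7, 21, 4))
  res <- euclidean_timecourse(a, b)
  perm <- sample(21)
  res_p <- euclidean_timecourse(a[, perm, , drop = FALSE],
                                b[, perm, , drop = FALSE])
  expect_equal(res$d, res_p$d, tolerance = 1e-12)
  expect_equal(res$var_within, res_p$var_within, tolerance = 1e-12)
  # direct oracle at t = 2 for group a
  m <- colMeans(a[, , 2])
  di <- apply(a[, , 2], 1, function(r) sqrt(sum((r - m)^2)))
  expect_equal(unname(res$var_within["a", 2]), var(di), tolerance = 1e-12)
  expect_error(euclidean_timecourse(a, b[, 1:20, , drop = FALSE]), "agree")
})

test_that("PCA identities: rank-1 input, ratio normalization, 2-feature
           correlation", {
  # rank-1: all samples proportional to one pattern
  v <- seq_len(21) / 10
  x <- outer(rnorm(30, sd = 2) + 3, v)
  p <- network_pca(x)
  expect_gt(p$explained[1], 0.999)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  # 2-feature toy with known correlation 0.9: PC1 = (1,1)/sqrt(2), 95 %
  set.seed(12)
  z <- matrix(rnorm(2 * 20000), ncol = 2) %*% chol(matrix(c(1, .9, .9, 1), 2))
  p2 <- network_pca(z)
  expect_equal(abs(p2$rotation[, 1]), rep(1 / sqrt(2), 2), tolerance = 0.02)
  expect_equal(p2$explained[1], 0.95, tolerance = 0.01)
})

test_that("PC scores reconstruct the standardized data", {
  set.seed(13)
  x <- matrix(rnorm(40 * 21), 40, 21)
  p <- network_pca(x)
  z <- scale(x, center = p$center, scale = p$scale)
  recon <- as.matrix(p$scores) %*% t(p$rotation)
  expect_lt(max(abs(recon - z)), 1e-9)
})

test_that("zero-variance features are dropped with a warning", {
  set.seed(14)
  x <- cbind(matrix(rnorm(60), 20, 3), 0.5)
  expect_warning(p <- network_pca(x), "zero-variance")
  expect_identical(ncol(p$rotation), 3L)
})

test_that("eigenvectors reshape to the symmetric area layout", {
  set.seed(15)
  x <- matrix(rnorm(50 * 21), 50, 21)
  p <- network_pca(x)
  m <- pca_component_matrix(p, 1, names(default_roi_map()))
  expect_identical(dim(m), c(6L, 6L))
  expect_equal(m, t(m))
  expect_equal(feature_vector(m), setNames(p$rotation[, 1], names(feature_vector(m))),
               tolerance = 1e-12)
})

test_that("well-separated Gaussian clusters classify nearly perfectly", {
  sim <- simulate_feature_matrix(20, effect_size = 5, seed = 16)
  fit <- lda_cv_classify(sim$x, sim$group, n_folds = 100, seed = 17)
  expect_gte(fit$mean_accuracy, 0.95)
  expect_identical(fit$n_train, 38L)
  # exactly k features enter every fold
  expect_true(all(colSums(!is.na(fit$selected)) == 10))
  expect_true(all(apply(fit$selected, 2, anyDuplicated) == 0))
  # folds hold out one subject per class
  grp <- as.integer(sim$group)
  expect_true(all(apply(fit$test_subjects, 2,
                        function(ix) sort(grp[ix])) == c(1, 2)))
})

test_that("classification is seed-reproducible and fold accuracies are
           {0, 0.5, 1}", {
  sim <- simulate_feature_matrix(10, effect_size = 1, seed = 18)
  a <- lda_cv_classify(sim$x, sim$group, n_folds = 30, seed = 19)
  b <- lda_cv_classify(sim$x, sim$group, n_folds = 30, seed = 19)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
  expect_true(all(a$fold_accuracy %in% c(0, 0.5, 1)))
  c <- lda_cv_classify(sim$x, sim$group, n_folds = 30, seed = 20)
  expect_false(identical(a$test_subjects, c$test_subjects))
})

test_that("label shuffling yields chance-level accuracy", {
  sim <- simulate_feature_matrix(20, effect_size = 2, seed = 21)
  fit <- lda_cv_classify(sim$x, sim$group, n_folds = 100, shuffle = TRUE,
                         seed = 22)
  expect_gte(fit$mean_accuracy, 0.35)
  expect_lte(fit$mean_accuracy, 0.65)
})

test_that("with no group effect, fitted accuracy is indistinguishable from
           the shuffled control", {
  sim <- simulate_feature_matrix(20, effect_size = 0, seed = 23)
  fit <- lda_cv_classify(sim$x, sim$group, n_folds = 100, seed = 24)
  shuf <- lda_cv_classify(sim$x, sim$group, n_folds = 100, shuffle = TRUE,
                          seed = 24)
  # both near 0.5; difference within binomial noise of 100 folds
  expect_lt(abs(fit$mean_accuracy - shuf$mean_accuracy), 0.15)
  expect_lt(abs(fit$mean_accuracy - 0.5), 0.15)
})

test_that("classifier input contracts are enforced", {
  sim <- simulate_feature_matrix(5, seed = 25)
  expect_error(lda_cv_classify(sim$x, sim$group, k_features = 22), "exceeds")
  expect_error(lda_cv_classify(sim$x, rep("A", 10)), "two classes")
  expect_error(lda_cv_classify(sim$x, sim$group, n_test = 3), "even")
})

test_that("the vectorized ANOVA F matches anova(lm(.))", {
  set.seed(26)
  x <- matrix(rnorm(30 * 4), 30, 4)
  g <- factor(rep(c("a", "b"), each = 15))
  x[g == "b", 2] <- x[g == "b", 2] + 1
  f <- plvnet:::anova_f(x, g)
  f_ref <- vapply(seq_len(4), function(j)
    anova(lm(x[, j] ~ g))[1, "F value"], numeric(1))
  expect_equal(unname(f), f_ref, tolerance = 1e-10)
})
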