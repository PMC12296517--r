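#' Euclidean distance between group-average network time courses
#'
#' At every time sample, averages the subject feature vectors (the 21
#' unique area-matrix entries) within each group and returns the Euclidean
#' norm of the group-mean difference, `d(t) = ||A_TS(t) - A_CO(t)||_2`,
#' together with the within-group variability: the variance across subjects
#' of each subject's Euclidean distance to its own group mean.
#'
#' @param features_a,features_b arrays `n_subjects x n_features x n_times`
#'   (a `n_subjects x n_features` matrix is treated as one time sample) for
#'   the two groups.
#' @param time optional time axis (ms) carried through to the output.
#' @return A `network_distance`: list with `d` (length n_times),
#'   `var_within` (2 x n_times matrix, rows named after the groups),
#'   the group-mean matrices (`mean_a`, `mean_b`) and `time`.
#' @export
euclidean_timecourse <- function(features_a, features_b, time = NULL) {
  as3d <- function(x) {
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
    stopifnot(length(dim(x)) == 3)
    x
  }
  a <- as3d(features_a); b <- as3d(features_b)
  if (dim(a)[2] != dim(b)[2] || dim(a)[3] != dim(b)[3])
    stop("feature arrays must agree in features and time samples")
  if (dim(a)[1] < 2 || dim(b)[1] < 2)
    stop("need >= 2 subjects per group")
  nt <- dim(a)[3]
  mean_a <- apply(a, c(2, 3), mean)
  mean_b <- apply(b, c(2, 3), mean)
  d <- sqrt(colSums((mean_a - mean_b)^2))
  within_var <- function(x, m) {
    # variance across subjects of ||x_i(t) - mean(t)||
    vapply(seq_len(nt), function(t) {
      di <- sqrt(colSums((t(x[, , t]) - m[, t])^2))
      var(di)
    }, numeric(1))
  }
  structure(
    list(d = d,
         var_within = rbind(a = within_var(a, mean_a),
                            b = within_var(b, mean_b)),
         mean_a = mean_a, mean_b = mean_b, time = time),
    class = "network_distance"
  )
}

#' PCA of connectivity feature vectors
#'
#' Principal component analysis of network feature vectors (rows = samples,
#' e.g. group-average vectors concatenated across groups and time; columns
#' = the 21 unique area connections). Features are mean-centered and scaled
#' to unit variance using the pooled (concatenated) data; zero-variance
#' features cannot be scaled and are dropped with a warning.
#'
#' @param x numeric matrix, samples x features.
#' @param ids optional data.frame of row annotations (e.g. group, time)
#'   carried into the score table.
#' @return A `network_pca`: `scores` (samples x components, with `ids`
#'   prepended when given), `explained` (variance ratios), `rotation`
#'   (eigenvectors, features x components), `dropped` (names/indices of
#'   zero-variance features), `center`, `scale`.
#' @export
network_pca <- function(x, ids = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("PCA needs >= 2 samples")
  sds <- apply(x, 2, sd)
  dropped <- which(sds < .Machine$double.eps^0.5)
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped),
            " zero-variance feature(s): cannot be scaled")
    x <- x[, -dropped, drop = FALSE]
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  if (!is.null(ids)) scores <- cbind(ids, as.data.frame(scores))
  structure(
    list(scores = scores, explained = explained, rotation = pc$rotation,
         dropped = dropped, center = pc$center, scale = pc$scale),
    class = "network_pca"
  )
}

#' Reshape a principal axis to the area adjacency layout
#'
#' @param pca a `network_pca` whose features are the 21 unique entries of a
#'   symmetric 6x6 matrix.
#' @param component which component to reshape.
#' @param area_names optional area names for dimnames.
#' @return Symmetric matrix with the eigenvector entries.
#' @export
pca_component_matrix <- function(pca, component = 1, area_names = NULL) {
  stopifnot(inherits(pca, "network_pca"))
  v <- pca$rotation[, component]
  features_to_matrix(v, area_names)
}

#' Synthetic two-group feature vectors
#'
#' Gaussian 21-feature vectors for classifier validation: `n_informative`
#' features are shifted by `effect_size` (in within-group SD units) in the
#' second group; the rest are pure noise. This is the fast feature-level
#' complement of the full cohort generator.
#'
#' @param n_per_group subjects per group.
#' @param effect_size standardized mean shift of the informative features.
#' @param n_features total features (default 21).
#' @param n_informative number of shifted features (default 10).
#' @param seed integer seed.
#' @return List with `x` (2 n_per_group x n_features matrix) and `group`
#'   (factor, "TS"/"CO").
#' @export
simulate_feature_matrix <- function(n_per_group = 20, effect_size = 1,
                                    n_features = 21, n_informative = 10,
                                    seed = 1L) {
  stopifnot(n_informative <= n_features)
  set.seed(seed)
  n <- 2L * n_per_group
  x <- matrix(rnorm(n * n_features), n, n_features)
  group <- factor(rep(c("TS", "CO"), each = n_per_group),
                  levels = c("TS", "CO"))
  x[group == "TS", seq_len(n_informative)] <-
    x[group == "TS", seq_len(n_informative)] + effect_size
  colnames(x) <- paste0("f", seq_len(n_features))
  list(x = x, group = group)
}

#' Cross-validated linear discriminant classification
#'
#' Repeated random-subsampling cross-validation of a two-class linear
#' discriminant on connectivity features. Per fold: one randomly chosen
#' test subject per class is held out (`n_test` total), the training set is
#' z-scored by its own mean/SD, the `k_features` most discriminative
#' features are selected by the one-way ANOVA F statistic on the training
#' data (ties broken toward the lower feature index), an LDA with pooled
#' within-class covariance (plus a small ridge, `1e-6` on the diagonal, for
#' singular cases) is fitted, and accuracy is measured on the held-out
#' subjects. With `shuffle = TRUE` the training labels are permuted within
#' each fold, giving the chance-level surrogate control (~50 %).
#'
#' @param features numeric matrix, subjects x features.
#' @param labels two-level factor (or coercible) of group labels.
#' @param n_folds number of folds (default 100).
#' @param n_test held-out subjects per fold (even; half per class).
#' @param k_features number of features entering the discriminant.
#' @param shuffle permute training labels per fold (surrogate control).
#' @param seed integer seed; folds and permutations derive from it.
#' @return A `plv_classification`: `fold_accuracy` (length `n_folds`,
#'   values in {0, 0.5, 1} for `n_test = 2`), `mean_accuracy`,
#'   `selected` (k_features x n_folds matrix of chosen feature indices),
#'   `test_subjects` (n_test x n_folds), `n_train`, `shuffle`, `seed`.
#' @examples
#' sim <- simulate_feature_matrix(10, effect_size = 3, seed = 2)
#' fit <- lda_cv_classify(sim$x, sim$group, n_folds = 20, seed = 3)
#' fit$mean_accuracy
#' @export
lda_cv_classify <- function(features, labels, n_folds = 100, n_test = 2,
                            k_features = 10, shuffle = FALSE, seed = 1L) {
  x <- as.matrix(features)
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two classes are required")
  if (n_test %% 2 != 0) stop("n_test must be even (balanced test folds)")
  if (k_features > ncol(x))
    stop("k_features exceeds the number of features")
  n_half <- n_test / 2
  idx_by_class <- split(seq_len(nrow(x)), labels)
  if (any(lengths(idx_by_class) <= n_half))
    stop("each class needs more subjects than it contributes to a test fold")

  set.seed(seed)
  fold_acc <- numeric(n_folds)
  selected <- matrix(NA_integer_, k_features, n_folds)
  test_subjects <- matrix(NA_integer_, n_test, n_folds)
  n_train <- as.integer(nrow(x) - n_test)

  for (fold in seq_len(n_folds)) {
    test <- c(vapply(idx_by_class,
                     function(ix) sample(ix, n_half), integer(n_half)))
    train <- setdiff(seq_len(nrow(x)), test)
    y_tr <- labels[train]
    if (shuffle) y_tr <- y_tr[sample(length(y_tr))]

    mu <- colMeans(x[train, , drop = FALSE])
    sg <- apply(x[train, , drop = FALSE], 2, sd)
    sg[sg < .Machine$double.eps] <- 1          # constant feature: center only
    z_tr <- sweep(sweep(x[train, , drop = FALSE], 2, mu), 2, sg, "/")
    z_te <- sweep(sweep(x[test, , drop = FALSE], 2, mu), 2, sg, "/")

    fstat <- anova_f(z_tr, y_tr)
    keep <- order(-fstat, seq_along(fstat))[seq_len(k_features)]
    w <- lda_direction(z_tr[, keep, drop = FALSE], y_tr)
    pred <- lda_predict(z_te[, keep, drop = FALSE], w)
    fold_acc[fold] <- mean(pred == labels[test])
    selected[, fold] <- keep
    test_subjects[, fold] <- test
  }

  structure(
    list(fold_accuracy = fold_acc,
         mean_accuracy = mean(fold_acc),
         selected = selected,
         test_subjects = test_subjects,
         n_train = n_train,
         n_folds = n_folds,
         k_features = k_features,
         shuffle = shuffle,
         seed = seed,
         classes = levels(labels)),
    class = "plv_classification"
  )
}

# One-way ANOVA F statistic per feature (two or more groups, vectorized
# closed form; equals anova(lm(x ~ g)) column by column).
anova_f <- function(x, g) {
  g <- factor(g)
  n <- nrow(x)
  k <- nlevels(g)
  gm <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (lev in levels(g)) {
    xi <- x[g == lev, , drop = FALSE]
    mi <- colMeans(xi)
    ssb <- ssb + nrow(xi) * (mi - gm)^2
    ssw <- ssw + colSums(sweep(xi, 2, mi)^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- msb / msw
  f[msw < .Machine$double.eps] <- Inf * sign(msb[msw < .Machine$double.eps])
  f[!is.finite(f) & msb < .Machine$double.eps] <- 0
  f
}

# Two-class LDA direction and midpoint threshold with a small ridge on the
# pooled covariance.
lda_direction <- function(x, y, ridge = 1e-6) {
  lev <- levels(y)
  x1 <- x[y == lev[1], , drop = FALSE]
  x2 <- x[y == lev[2], , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  s <- ((nrow(x1) - 1) * cov_safe(x1) + (nrow(x2) - 1) * cov_safe(x2)) /
    (nrow(x) - 2)
  s <- s + diag(ridge, ncol(x))
  w <- solve(s, m1 - m2)
  list(w = w, threshold = sum(w * (m1 + m2) / 2), classes = lev)
}

cov_safe <- function(x) {
  if (nrow(x) < 2) return(matrix(0, ncol(x), ncol(x)))
  stats::cov(x)
}

lda_predict <- function(x, fit) {
  score <- drop(x %*% fit$w)
  factor(ifelse(score > fit$threshold, fit$classes[1], fit$classes[2]),
         levels = fit$classes)
}

#' @export
print.plv_classification <- function(x, ...) {
  cat(sprintf(
    "<plv_classification> %d folds, %d train / %d test, top-%d features%s\n",
    x$n_folds, x$n_train, nrow(x$test_subjects),
    x$k_features, if (x$shuffle) " [label-shuffled control]" else ""))
  cat(sprintf("  mean accuracy: %.1f %%\n", 100 * x$mean_accuracy))
  invisible(x)
}
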