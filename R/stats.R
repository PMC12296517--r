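#' Pointwise significance map of event-related rPLV increases
#'
#' For every area connection and time sample, a one-sample t test across
#' subjects of rPLV > 0 (one-sided, greater), reported as `-log10(p)`.
#' Connections/samples with zero across-subject variance are assigned
#' p = 1 (map value 0) rather than an undefined statistic. The map is
#' deliberately left uncorrected (exploratory use); scalar group contrasts
#' go through [fdr_adjust()].
#'
#' @param x array `n_subjects x n_connections x n_times` of rPLV; an
#'   `n_subjects x n_times` matrix is treated as a single connection.
#' @param conn_names,time optional dimnames for the output.
#' @return `significance_map`: matrix n_connections x n_times of
#'   `-log10(p)`, attribute `p` with the raw p values.
#' @export
pointwise_increase_map <- function(x, conn_names = NULL, time = NULL) {
  if (is.matrix(x)) x <- array(x, c(nrow(x), 1L, ncol(x)))
  stopifnot(length(dim(x)) == 3)
  n <- dim(x)[1]
  if (n < 3) stop("need >= 3 subjects for the pointwise test")
  m <- apply(x, c(2, 3), mean)
  s <- apply(x, c(2, 3), sd)
  tstat <- m / (s / sqrt(n))
  p <- pt(tstat, df = n - 1, lower.tail = FALSE)
  p[s < .Machine$double.eps] <- 1       # degenerate: no spread, no evidence
  map <- -log10(p)
  if (!is.null(conn_names)) rownames(map) <- conn_names
  if (!is.null(time)) colnames(map) <- time
  attr(map, "p") <- p
  class(map) <- c("significance_map", class(map))
  map
}

#' Mann-Whitney U contrast between two groups
#'
#' Two-sided rank-sum comparison with tie correction. Reports the U
#' statistic for the first sample, the normal-approximation score
#' `Z = (U - n1 n2 / 2) / sigma_U` (tie-corrected, no continuity
#' correction), the p value from [stats::wilcox.test()] (exact for small
#' tie-free samples, normal approximation otherwise), the effect size
#' `r = |Z| / sqrt(n1 + n2)`, and group medians/IQRs.
#'
#' @param x,y numeric vectors (group samples).
#' @param exact passed to [stats::wilcox.test()] (default: its own rule).
#' @return A `group_comparison` list: `u`, `z`, `p`, `r`, `median`, `iqr`,
#'   `n`.
#' @examples
#' mann_whitney_compare(c(1, 2, 3), c(4, 5, 6))$p  # exact, 0.1
#' @export
mann_whitney_compare <- function(x, y, exact = NULL) {
  if (length(x) < 1 || length(y) < 1) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  u <- unname(wt$statistic)
  # tie-corrected normal approximation
  all_v <- c(x, y)
  nn <- n1 + n2
  ties <- table(all_v)
  sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z <- if (sigma2 > 0) (u - n1 * n2 / 2) / sqrt(sigma2) else 0
  structure(
    list(u = u, z = z, p = wt$p.value, r = abs(z) / sqrt(nn),
         median = c(x = median(x), y = median(y)),
         iqr = c(x = unname(diff(quantile(x, c(0.25, 0.75)))),
                 y = unname(diff(quantile(y, c(0.25, 0.75))))),
         n = c(n1, n2)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, Z = %.2f, p = %.4g, r = %.2f\n",
              x$u, x$z, x$p, x$r))
  cat(sprintf("  group 1: Mdn = %.3g (IQR %.3g), n = %d\n",
              x$median[1], x$iqr[1], x$n[1]))
  cat(sprintf("  group 2: Mdn = %.3g (IQR %.3g), n = %d\n",
              x$median[2], x$iqr[2], x$n[2]))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values (monotone non-decreasing in rank); a thin
#' validated wrapper around [stats::p.adjust()].
#'
#' @param p vector of p values in (0, 1].
#' @return Adjusted p values, same length.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.04))
#' @export
fdr_adjust <- function(p) {
  stopifnot(all(p > 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Behavioral performance summary per subject
#'
#' Reaction times are filtered to the open interval (150, 1500) ms to drop
#' anticipatory and excessively delayed responses; accuracy is the
#' percentage of correct responses over all trials; anticipatory responses
#' (presses between S1 and S2) are counted separately.
#'
#' @param behavior per-trial behavioral records (one or more subjects):
#'   columns `subject_id`, `side`, `rt_ms`, `anticipatory`, `correct`.
#' @return data.frame, one row per subject: median/mean RT per side (of
#'   correct, filtered trials), accuracy (%), anticipatory count, number of
#'   RTs surviving the filter, and a validity flag (FALSE when no trials
#'   survive).
#' @export
behavioral_summary <- function(behavior) {
  stopifnot(all(c("subject_id", "side", "rt_ms", "anticipatory", "correct")
                %in% names(behavior)))
  out <- lapply(split(behavior, behavior$subject_id), function(b) {
    keep <- b$correct & !b$anticipatory &
      !is.na(b$rt_ms) & b$rt_ms > 150 & b$rt_ms < 1500
    rt_side <- function(s) {
      v <- b$rt_ms[keep & b$side == s]
      c(median = if (length(v)) median(v) else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_)
    }
    l <- rt_side("left"); r <- rt_side("right")
    data.frame(
      subject_id = b$subject_id[1],
      rt_median_left = l["median"], rt_mean_left = l["mean"],
      rt_median_right = r["median"], rt_mean_right = r["mean"],
      rt_mean = if (any(keep)) mean(b$rt_ms[keep]) else NA_real_,
      accuracy = 100 * mean(b$correct),
      anticipatory_n = sum(b$anticipatory),
      n_valid_rt = sum(keep),
      valid = any(keep),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Regression of a behavioral outcome on global efficiency
#'
#' Ordinary least-squares simple regression (e.g. mean reaction time on
#' post-S2 global efficiency). Reports R^2, F(1, n - 2), the slope and the
#' p value; p values of a family of such models (group x window x outcome)
#' should be jointly passed through [fdr_adjust()].
#'
#' @param e_glob per-subject global efficiency (predictor).
#' @param outcome per-subject behavioral measure (response).
#' @return list: `r_squared`, `f`, `df`, `p`, `slope`, `intercept`, `n`.
#' @export
efficiency_rt_regression <- function(e_glob, outcome) {
  keep <- complete.cases(e_glob, outcome)
  e_glob <- e_glob[keep]; outcome <- outcome[keep]
  n <- length(e_glob)
  if (n < 3) stop("need >= 3 subjects")
  if (sd(e_glob) < .Machine$double.eps) stop("zero-variance predictor")
  fit <- lm(outcome ~ e_glob)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  list(
    r_squared = sm$r.squared,
    f = unname(fstat[1]),
    df = unname(fstat[2:3]),
    p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n = n
  )
}

#' Chi-square worked example for demographic tables
#'
#' Pearson chi-square (no continuity correction) on a 2x2 group-by-trait
#' count table, e.g. male/female per group.
#'
#' @param yes1,n1 trait count and total in group 1.
#' @param yes2,n2 trait count and total in group 2.
#' @return list: `statistic`, `df`, `p`.
#' @examples
#' group_chisq(16, 20, 16, 20)$statistic  # identical proportions -> 0
#' @export
group_chisq <- function(yes1, n1, yes2, n2) {
  tab <- matrix(c(yes1, n1 - yes1, yes2, n2 - yes2), nrow = 2)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
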