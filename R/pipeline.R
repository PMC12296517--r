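#' Windowed network analysis of a whole cohort
#'
#' Runs [subject_connectivity()] for every subject and summarizes each
#' analysis window: the 21-entry area feature vector, the mean network
#' rPLV over all electrode pairs, and the graph metrics (global efficiency
#' and average clustering, binary and weighted). Behavioral records are
#' summarized per subject.
#'
#' @param cohort a `plv_cohort` (or any list of `list(epochs, behavior)`
#'   elements).
#' @param windows named list of half-open ms analysis windows.
#' @param baseline baseline window, ms.
#' @param freqs,n_cycles,sample_step,by_condition passed to
#'   [subject_connectivity()]. `sample_step > 1` evaluates PLV on a coarser
#'   grid (the window means of the smooth PLV time course are barely
#'   affected; useful for simulation studies).
#' @param roi an `roi_map`.
#' @param keep_timecourse keep each subject's 21-connection area rPLV time
#'   course (needed for [euclidean_timecourse()] / [network_pca()] /
#'   [pointwise_increase_map()] over time).
#' @return A `cohort_analysis`: list with
#'   `features` (n_subjects x 21 x n_windows array),
#'   `metrics` (tidy data.frame: subject, group, window, mean_rplv,
#'   e_glob and clustering per mode), `behavior` (per-subject summary with
#'   group), `timecourses` (optional n_subjects x 21 x n_times array plus
#'   `time`), `subjects`, `groups`, `windows`, and the analysis settings.
#' @export
analyze_cohort <- function(cohort,
                           windows = list(S1 = c(-3200, -2700),
                                          S2 = c(0, 500)),
                           baseline = c(-3700, -3200),
                           freqs = 4:7, n_cycles = 5, sample_step = 1L,
                           by_condition = TRUE,
                           roi = default_roi_map(),
                           keep_timecourse = FALSE) {
  subjects <- cohort$subjects
  stopifnot(length(subjects) >= 1, !is.null(names(windows)))
  n_sub <- length(subjects)
  ids <- vapply(subjects, function(s) s$epochs$subject_id, character(1))
  groups <- vapply(subjects, function(s) s$epochs$group, character(1))

  features <- array(NA_real_, c(n_sub, 21L, length(windows)),
                    dimnames = list(ids, NULL, names(windows)))
  metrics <- vector("list", n_sub * length(windows))
  timecourses <- NULL
  tc_time <- NULL
  behavior <- vector("list", n_sub)

  for (i in seq_len(n_sub)) {
    es <- subjects[[i]]$epochs
    pc <- subject_connectivity(es, freqs = freqs, n_cycles = n_cycles,
                               baseline = baseline, windows = windows,
                               sample_step = sample_step,
                               by_condition = by_condition)
    for (w in seq_along(windows)) {
      am <- area_adjacency(pc, roi, windows[[w]])
      features[i, , w] <- am$feature_vector
      if (w == 1) dimnames(features)[[2]] <- names(am$feature_vector)
      gs <- graph_summary(pc, roi, windows[[w]])
      gs$window <- names(windows)[w]
      gs$mean_rplv <- mean_network_rplv(pc, windows[[w]])
      metrics[[(i - 1) * length(windows) + w]] <- gs
    }
    if (keep_timecourse) {
      tc <- area_timecourse(pc, roi)
      if (is.null(timecourses)) {
        timecourses <- array(NA_real_, c(n_sub, nrow(tc), ncol(tc)),
                             dimnames = list(ids, rownames(tc), NULL))
        tc_time <- attr(tc, "time")
      }
      timecourses[i, , ] <- tc
    }
    behavior[[i]] <- behavioral_summary(subjects[[i]]$behavior)
    behavior[[i]]$group <- es$group
  }

  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL
  structure(
    list(features = features,
         metrics = metrics,
         behavior = do.call(rbind, c(behavior, list(make.row.names = FALSE))),
         timecourses = timecourses,
         time = tc_time,
         subjects = ids,
         groups = groups,
         windows = windows,
         baseline = baseline,
         freqs = freqs,
         n_cycles = n_cycles,
         sample_step = sample_step),
    class = "cohort_analysis"
  )
}

#' Tidy table of area-matrix entries
#'
#' @param analysis a `cohort_analysis`.
#' @return data.frame: subject, group, window, area_i, area_j, rplv — the
#'   on-disk exchange format for the area-level networks.
#' @export
area_matrix_table <- function(analysis) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  fv <- analysis$features
  conn <- dimnames(fv)[[2]]
  parts <- strsplit(conn, "~", fixed = TRUE)
  out <- expand.grid(subject = dimnames(fv)[[1]], conn = seq_along(conn),
                     window = dimnames(fv)[[3]], stringsAsFactors = FALSE)
  out$group <- analysis$groups[match(out$subject, analysis$subjects)]
  out$area_i <- vapply(parts, `[`, character(1), 1)[out$conn]
  out$area_j <- vapply(parts, `[`, character(1), 2)[out$conn]
  out$rplv <- fv[cbind(match(out$subject, dimnames(fv)[[1]]), out$conn,
                       match(out$window, dimnames(fv)[[3]]))]
  out$conn <- NULL
  out[, c("subject", "group", "window", "area_i", "area_j", "rplv")]
}

#' Group contrast of a windowed network metric
#'
#' Mann-Whitney U contrasts (TS vs CO) of one metric column for every
#' analysis window, with BH-adjusted p values across windows.
#'
#' @param analysis a `cohort_analysis`.
#' @param measure metric column (e.g. `"mean_rplv"`, `"e_glob_binary"`,
#'   `"e_glob_weighted"`, `"clustering_binary"`).
#' @return data.frame, one row per window: medians/IQRs, U, Z, p, r,
#'   p_fdr.
#' @export
compare_groups <- function(analysis, measure = "mean_rplv") {
  stopifnot(inherits(analysis, "cohort_analysis"),
            measure %in% names(analysis$metrics))
  m <- analysis$metrics
  rows <- lapply(unique(m$window), function(w) {
    ts <- m[m$window == w & m$group == "TS", measure]
    co <- m[m$window == w & m$group == "CO", measure]
    gc <- mann_whitney_compare(ts, co)
    data.frame(window = w, measure = measure,
               median_ts = gc$median[1], iqr_ts = gc$iqr[1],
               median_co = gc$median[2], iqr_co = gc$iqr[2],
               u = gc$u, z = gc$z, p = gc$p, r = gc$r,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- fdr_adjust(out$p)
  out
}

#' End-to-end synthetic study
#'
#' Generates a cohort from `config`, runs the windowed network analysis,
#' and assembles the group-level layer: Mann-Whitney contrasts of mean
#' network rPLV and global efficiency per window, the per-window LDA
#' cross-validation (plus label-shuffled control), and the
#' efficiency-reaction-time regressions per group and window (family-wise
#' BH adjusted).
#'
#' @param config a [cohort_config()].
#' @param windows named list of analysis windows (ms).
#' @param sample_step PLV evaluation stride (see [analyze_cohort()]).
#' @param n_folds,k_features classifier settings.
#' @param efficiency_mode `"binary"` or `"weighted"` efficiency for the
#'   contrasts and regressions.
#' @param seed seed for the classifier folds (cohort randomness comes from
#'   `config$seed`).
#' @return List: `analysis`, `contrasts` (rPLV + efficiency + clustering),
#'   `classification` (per window: fitted and shuffled), `regressions`
#'   (tidy data.frame with p_fdr), `config`.
#' @export
run_study <- function(config = cohort_config(),
                      windows = list(S1 = c(-3200, -2700), S2 = c(0, 500)),
                      sample_step = 1L, n_folds = 100, k_features = 10,
                      efficiency_mode = c("binary", "weighted"),
                      seed = config$seed) {
  efficiency_mode <- match.arg(efficiency_mode)
  eff_col <- paste0("e_glob_", efficiency_mode)
  clu_col <- paste0("clustering_", efficiency_mode)

  cohort <- generate_cohort(config)
  analysis <- analyze_cohort(cohort, windows = windows,
                             sample_step = sample_step)

  contrasts <- rbind(compare_groups(analysis, "mean_rplv"),
                     compare_groups(analysis, eff_col),
                     compare_groups(analysis, clu_col))
  contrasts$p_fdr <- fdr_adjust(contrasts$p)

  grp <- factor(analysis$groups, levels = c("TS", "CO"))
  classification <- lapply(seq_along(windows), function(w) {
    x <- analysis$features[, , w]
    list(window = names(windows)[w],
         fitted = lda_cv_classify(x, grp, n_folds = n_folds,
                                  k_features = k_features, seed = seed + w),
         shuffled = lda_cv_classify(x, grp, n_folds = n_folds,
                                    k_features = k_features, shuffle = TRUE,
                                    seed = seed + w))
  })
  names(classification) <- names(windows)

  beh <- analysis$behavior
  m <- analysis$metrics
  reg <- list()
  for (w in names(windows)) {
    for (g in c("TS", "CO")) {
      sel <- m$window == w & m$group == g
      subj <- m$subject_id[sel]
      rt <- beh$rt_mean[match(subj, beh$subject_id)]
      fit <- efficiency_rt_regression(m[sel, eff_col], rt)
      reg[[length(reg) + 1]] <- data.frame(
        window = w, group = g, outcome = "rt_mean",
        r_squared = fit$r_squared, f = fit$f, p = fit$p,
        slope = fit$slope, n = fit$n, stringsAsFactors = FALSE)
    }
  }
  regressions <- do.call(rbind, reg)
  regressions$p_fdr <- fdr_adjust(regressions$p)

  list(analysis = analysis, contrasts = contrasts,
       classification = classification, regressions = regressions,
       config = config)
}
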