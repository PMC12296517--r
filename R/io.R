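#' Write an epoch set to the on-disk container
#'
#' One directory per subject: `data.bin`, the channels x samples x trials
#' array as little-endian float32 in R array (column-major) order, plus
#' `meta.json` (labels, sampling rate, time axis, group) and `trials.csv`
#' (side, validity).
#'
#' @param epochs an `epoch_set`.
#' @param dir parent directory; the subject subdirectory is created.
#' @return The subject directory, invisibly.
#' @export
write_epoch_set <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  sd <- file.path(dir, epochs$subject_id)
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(sd, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(epochs$data), con, size = 4L, endian = "little")
  meta <- list(
    subject_id = epochs$subject_id,
    group = epochs$group,
    dim = dim(epochs$data),
    channel_labels = epochs$channel_labels,
    fs = epochs$fs,
    time_axis = epochs$time_axis
  )
  jsonlite::write_json(meta, file.path(sd, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(epochs$trial_table, file.path(sd, "trials.csv"),
                   row.names = FALSE)
  invisible(sd)
}

#' Read an epoch set from the on-disk container
#'
#' @param dir a subject directory written by [write_epoch_set()].
#' @return An `epoch_set` (float32 round-trip precision).
#' @export
read_epoch_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
  trials <- utils::read.csv(file.path(dir, "trials.csv"),
                            stringsAsFactors = FALSE)
  structure(
    list(subject_id = meta$subject_id,
         group = meta$group,
         data = array(x, d),
         time_axis = as.numeric(meta$time_axis),
         channel_labels = as.character(meta$channel_labels),
         fs = meta$fs,
         trial_table = trials,
         sim_truth = NULL),
    class = "epoch_set"
  )
}

#' Write a pairwise connectivity result to the container format
#'
#' Stores the band-averaged rPLV matrix as little-endian float32
#' (`rplv.bin`, pairs x samples in column-major order) with a JSON
#' manifest (`manifest.json`: pair labels, band, baseline window,
#' evaluated times, subject/group, unusable pairs).
#'
#' @param pc a `pair_connectivity`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_connectivity <- function(pc, dir) {
  stopifnot(inherits(pc, "pair_connectivity"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "rplv.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(pc$rplv), con, size = 4L, endian = "little")
  manifest <- list(
    subject_id = pc$subject_id, group = pc$group,
    dim = dim(pc$rplv),
    pair_i = pc$pair_labels[1, ], pair_j = pc$pair_labels[2, ],
    freqs = pc$freqs, n_cycles = pc$n_cycles,
    baseline = pc$baseline, time = pc$time,
    channel_labels = pc$channel_labels,
    unusable = which(pc$unusable),
    sample_step = pc$sample_step
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a pairwise connectivity result written by [write_connectivity()]
#'
#' @param dir the container directory.
#' @return A `pair_connectivity` (float32 round-trip precision; PLV and
#'   edge-validity fields are not stored).
#' @export
read_connectivity <- function(dir) {
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  d <- as.integer(m$dim)
  con <- file(file.path(dir, "rplv.bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
  labs <- as.character(m$channel_labels)
  unusable <- logical(d[1])
  unusable[as.integer(m$unusable)] <- TRUE
  structure(
    list(rplv = matrix(x, d[1], d[2]),
         plv = NULL,
         pairs = pair_index(length(labs)),
         pair_labels = rbind(as.character(m$pair_i), as.character(m$pair_j)),
         time = as.numeric(m$time),
         out_idx = NULL,
         baseline_cols = which(as.numeric(m$time) >= m$baseline[1] &
                                 as.numeric(m$time) < m$baseline[2]),
         baseline = as.numeric(m$baseline),
         freqs = as.numeric(m$freqs),
         n_cycles = m$n_cycles,
         valid = NULL,
         unusable = unusable,
         channel_labels = labs,
         subject_id = m$subject_id,
         group = m$group,
         n_trials = NULL,
         sample_step = m$sample_step),
    class = "pair_connectivity"
  )
}

#' Write a cohort (epochs + behavioral log)
#'
#' Subject subdirectories via [write_epoch_set()] plus a combined
#' `behavior.csv` (subject_id, trial, side, rt_ms, anticipatory, correct,
#' group).
#'
#' @param cohort a `plv_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "plv_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in cohort$subjects) write_epoch_set(s$epochs, dir)
  utils::write.csv(behavior_table(cohort), file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding subject subdirectories and `behavior.csv`.
#' @return A `plv_cohort` (without generator config or ground truth).
#' @export
read_cohort <- function(dir) {
  beh <- utils::read.csv(file.path(dir, "behavior.csv"),
                         stringsAsFactors = FALSE)
  subdirs <- list.dirs(dir, recursive = FALSE)
  subjects <- lapply(subdirs, function(sd) {
    es <- read_epoch_set(sd)
    list(epochs = es,
         behavior = beh[beh$subject_id == es$subject_id,
                        setdiff(names(beh), "group")])
  })
  names(subjects) <- vapply(subjects, function(s) s$epochs$subject_id,
                            character(1))
  structure(list(subjects = subjects, config = NULL), class = "plv_cohort")
}
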