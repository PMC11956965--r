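#' Assemble and validate a session recording
#'
#' A session bundles the conditioned-or-raw deconvolved activity matrix
#' (neurons x frames, nonnegative), the frame clock, the trial-event table,
#' a one-dimensional locomotion trace and metadata. Times are seconds from
#' session start; frame `i` (0-based) covers `[i/frame_rate, (i+1)/frame_rate)`.
#'
#' @param activity numeric matrix, neurons x frames, nonnegative.
#' @param trials trial table as produced by [generate_trials()] (columns
#'   `index`, `odor1`, `odor2`, `delay`, `is_reverse`, `is_match`,
#'   `odor1_onset`, `odor2_onset`, `rewarded`, `correct`,
#'   `first_lick_latency` and the list column `licks`).
#' @param locomotion numeric vector with one displacement value per frame.
#' @param cfg the [task_config()] the session was recorded under.
#' @param metadata named list; `animal`, `day` and `condition`
#'   (`"standard-only"` or `"with-reverse"`) are kept if present.
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(activity, trials, locomotion, cfg,
                              metadata = list()) {
  rec <- structure(list(
    activity = activity,
    frame_rate = cfg$frame_rate,
    trials = trials,
    locomotion = locomotion,
    cfg = cfg,
    metadata = metadata
  ), class = "session_recording")
  validate_session(rec)
  rec
}

#' Validate a session recording
#'
#' Checks every invariant of the session data model: nonnegative activity,
#' locomotion length equal to the frame count, sorted lick times, the
#' match-flag identity `is_match == (odor1 == odor2)`, second-odor onsets
#' consistent with `odor1_onset + odor_duration + delay`, and full frame
#' coverage of every trial window (through the end of the response window).
#' Violations raise a `seqtime_validation_error`.
#'
#' @param rec a `session_recording`.
#' @return `rec`, invisibly.
#' @export
validate_session <- function(rec) {
  assert_that(is.matrix(rec$activity) && is.numeric(rec$activity),
              "activity must be a numeric matrix")
  if (length(rec$activity) && min(rec$activity) < 0)
    validation_error("activity contains negative entries")
  n_frames <- ncol(rec$activity)
  assert_that(length(rec$locomotion) == n_frames,
              sprintf("locomotion has %d values for %d frames",
                      length(rec$locomotion), n_frames))
  tr <- rec$trials
  needed <- c("index", "odor1", "odor2", "delay", "is_reverse", "is_match",
              "odor1_onset", "odor2_onset", "licks")
  missing <- setdiff(needed, names(tr))
  if (length(missing))
    format_error(paste("trial table lacks column(s):",
                       paste(missing, collapse = ", ")))
  cfg <- rec$cfg
  bad_odor <- !(tr$odor1 %in% cfg$odor_labels) |
    !(tr$odor2 %in% cfg$odor_labels)
  if (any(bad_odor))
    validation_error("trial table contains unknown odor labels")
  if (any(tr$is_match != (tr$odor1 == tr$odor2)))
    validation_error("is_match inconsistent with odor identities")
  if (any(abs(tr$odor2_onset -
              (tr$odor1_onset + cfg$odor_duration + tr$delay)) > 1e-6))
    validation_error("odor2_onset inconsistent with odor1_onset + odor + delay")
  for (i in seq_len(nrow(tr))) {
    l <- tr$licks[[i]]
    if (length(l) && is.unsorted(l))
      validation_error(sprintf("licks of trial %d are not sorted", tr$index[i]))
  }
  trial_end <- tr$odor2_onset + cfg$odor_duration + cfg$response_window
  last_time <- n_frames / rec$frame_rate
  over <- which(trial_end > last_time + 1e-9 | tr$odor1_onset < 0)
  if (length(over))
    validation_error(sprintf(
      "trial window(s) outside recorded frames: trial(s) %s",
      paste(tr$index[over], collapse = ", ")))
  invisible(rec)
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("session_recording: %d neurons x %d frames (%.2f Hz), %d trials\n",
              nrow(x$activity), ncol(x$activity), x$frame_rate,
              nrow(x$trials)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             unlist(x$metadata, use.names = FALSE),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

trials_to_df <- function(trials) {
  out <- trials
  out$licks <- vapply(trials$licks, function(l)
    paste(fmt_num(l), collapse = ";"), character(1))
  out
}

trials_from_df <- function(df) {
  df$licks <- lapply(strsplit(ifelse(is.na(df$licks), "", df$licks), ";",
                              fixed = TRUE),
                     function(s) as.numeric(s[nzchar(s)]))
  df
}

#' Write a session container
#'
#' The on-disk session container is a directory of plain-text files:
#' `meta.json` (frame rate, task configuration, metadata), `activity.tsv`
#' (one row per neuron, `%.17g` formatting so doubles round-trip exactly),
#' `locomotion.tsv` and `trials.csv` (lick times semicolon-joined). Two
#' writes of the same object produce byte-identical payload files.
#'
#' @param rec a validated `session_recording`.
#' @param path directory to create (overwritten if it already exists).
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path) {
  validate_session(rec)
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok) io_error(sprintf("cannot create session directory '%s'", path))
  cfg <- rec$cfg
  meta <- list(
    format = "seqtime-session/1",
    frame_rate = cfg$frame_rate,
    n_neurons = nrow(rec$activity),
    n_frames = ncol(rec$activity),
    task = list(
      odor_labels = cfg$odor_labels,
      odor_duration = cfg$odor_duration,
      delay_short = unname(min(cfg$delay_map)),
      delay_long = unname(max(cfg$delay_map)),
      counterbalance = cfg$counterbalance,
      reverse_fraction = cfg$reverse_fraction,
      n_blocks = cfg$n_blocks,
      trials_per_block = cfg$trials_per_block,
      response_window = cfg$response_window,
      iti = cfg$iti
    ),
    metadata = rec$metadata
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(path, "meta.json"))
  act <- if (nrow(rec$activity) == 0L) character(0) else
    apply(rec$activity, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(act, file.path(path, "activity.tsv"))
  writeLines(fmt_num(rec$locomotion), file.path(path, "locomotion.tsv"))
  utils::write.csv(trials_to_df(rec$trials),
                   file.path(path, "trials.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a session container
#'
#' Reads a directory written by [write_session()] and returns a fully
#' validated [session_recording()]. A missing payload file raises a
#' `seqtime_format_error` naming it; invariant violations (negative
#' activity, trial windows outside the frame range, ...) raise a
#' `seqtime_validation_error`.
#'
#' @param path session directory.
#' @return a `session_recording`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) io_error(sprintf("no session directory '%s'", path))
  for (f in c("meta.json", "activity.tsv", "locomotion.tsv", "trials.csv"))
    if (!file.exists(file.path(path, f)))
      format_error(sprintf("session container lacks '%s'", f))
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"),
                             simplifyVector = TRUE)
  for (f in c("frame_rate", "n_neurons", "n_frames", "task"))
    if (is.null(meta[[f]]))
      format_error(sprintf("meta.json lacks field '%s'", f))
  tk <- meta$task
  cfg <- task_config(
    odor_labels = tk$odor_labels,
    odor_duration = tk$odor_duration,
    delay_short = tk$delay_short,
    delay_long = tk$delay_long,
    counterbalance = isTRUE(tk$counterbalance),
    reverse_fraction = tk$reverse_fraction,
    n_blocks = tk$n_blocks,
    trials_per_block = tk$trials_per_block,
    response_window = tk$response_window,
    frame_rate = meta$frame_rate,
    iti = tk$iti %||% 10
  )
  n_neurons <- meta$n_neurons
  n_frames <- meta$n_frames
  vals <- scan(file.path(path, "activity.tsv"), what = double(),
               quiet = TRUE)
  if (length(vals) != n_neurons * n_frames)
    format_error(sprintf(
      "activity.tsv has %d values, expected %d x %d",
      length(vals), n_neurons, n_frames))
  activity <- matrix(vals, nrow = n_neurons, ncol = n_frames, byrow = TRUE)
  locomotion <- scan(file.path(path, "locomotion.tsv"), what = double(),
                     quiet = TRUE)
  trials <- trials_from_df(utils::read.csv(file.path(path, "trials.csv"),
                                           stringsAsFactors = FALSE))
  md <- meta$metadata
  if (is.null(md) || (is.list(md) && !length(md))) md <- list()
  session_recording(activity, trials, locomotion, cfg,
                    metadata = as.list(md))
}
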