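#' Conditioning parameters
#'
#' Defaults follow the published pre-processing chain: a rolling mean over
#' 10 frames (0.32 s at 30.9 Hz), a hard floor that zeroes z-scores below 2
#' so small events within the noise range are excluded, and 5-frame
#' (0.16 s) analysis bins.
#'
#' @param smooth_window rolling-mean window in frames (default 10).
#' @param floor_z z-score threshold below which values are zeroed (default 2).
#' @param bin_frames frames per analysis bin (default 5).
#' @return a list of class `conditioning_params`.
#' @export
conditioning_params <- function(smooth_window = 10, floor_z = 2,
                                bin_frames = 5) {
  assert_that(is_count(smooth_window) && smooth_window >= 1 &&
                is_count(bin_frames) && bin_frames >= 1 &&
                is_scalar_num(floor_z) && floor_z > 0,
              "conditioning parameters must be positive", config_error)
  structure(list(smooth_window = as.integer(smooth_window),
                 floor_z = floor_z,
                 bin_frames = as.integer(bin_frames)),
            class = c("conditioning_params", "list"))
}

#' Condition deconvolved signals
#'
#' Per neuron: centered rolling mean over `smooth_window` frames (edges
#' shrink to the available frames), z-score over the whole session, then
#' entries below `floor_z` set to zero. The output stays on the z-score
#' scale ("firing rate (STD)"). A zero-variance neuron yields an all-zero
#' row rather than an error.
#'
#' @param raw nonnegative numeric matrix, neurons x frames.
#' @param params a [conditioning_params()].
#' @return conditioned matrix of the same shape.
#' @export
condition_signal <- function(raw, params = conditioning_params()) {
  assert_that(is.matrix(raw) && is.numeric(raw), "raw must be a numeric matrix")
  if (length(raw) && min(raw) < 0)
    validation_error("raw activity contains negative entries")
  if (nrow(raw) == 0L || ncol(raw) == 0L) return(raw)
  sm <- t(apply(raw, 1L, roll_mean_center, w = params$smooth_window))
  z <- zscore_rows(sm)
  z[z < params$floor_z] <- 0
  z
}

#' Align activity to first-odor onsets
#'
#' Extracts, for every trial, the frames from `odor1_onset + window[1]` to
#' `odor1_onset + window[2]` and averages them in consecutive groups of
#' `bin_frames`; a partial trailing bin is dropped, never padded. The frame
#' containing time `t` is `floor(t * frame_rate)` (0-based frames covering
#' `[i/fr, (i+1)/fr)`).
#'
#' @param rec a [session_recording()] (conditioned activity expected).
#' @param window two-element window in seconds around first-odor onset
#'   (default `c(-2, 11)`, the union of the baseline window and the
#'   mutual-information display range).
#' @param bin_frames frames per bin (default 5).
#' @param trials optional subset of trial indices (rows of the trial table).
#' @return an `aligned_activity` object: list with `tensor` (neurons x
#'   trials x bins), `time_axis` (bin-center times in seconds relative to
#'   first-odor onset), `bin_frames`, `bin_seconds`, `window`, `frame_rate`
#'   and `trial_index` (row indices into the session's trial table).
#' @export
align <- function(rec, window = c(-2, 11), bin_frames = 5, trials = NULL) {
  assert_that(length(window) == 2L && window[2] > window[1],
              "window must be an increasing pair of seconds", config_error)
  fr <- rec$frame_rate
  tr <- rec$trials
  sel <- trials %||% seq_len(nrow(tr))
  n_frames_win <- as.integer(floor((window[2] - window[1]) * fr))
  n_bins <- n_frames_win %/% bin_frames
  n_used <- n_bins * bin_frames
  start_frame <- as.integer(floor((tr$odor1_onset[sel] + window[1]) * fr))
  bad <- which(start_frame < 0L | start_frame + n_used > ncol(rec$activity))
  if (length(bad))
    validation_error(sprintf(
      "alignment window exceeds the recording for trial(s) %s",
      paste(tr$index[sel][bad], collapse = ", ")))
  binmat <- matrix(0, n_used, n_bins)
  binmat[cbind(seq_len(n_used), rep(seq_len(n_bins), each = bin_frames))] <-
    1 / bin_frames
  tensor <- array(0, dim = c(nrow(rec$activity), length(sel), n_bins))
  for (k in seq_along(sel)) {
    fidx <- start_frame[k] + seq_len(n_used)  # 1-based frame indices
    tensor[, k, ] <- rec$activity[, fidx, drop = FALSE] %*% binmat
  }
  time_axis <- window[1] + ((seq_len(n_bins) - 1) * bin_frames +
                              bin_frames / 2) / fr
  structure(list(
    tensor = tensor,
    time_axis = time_axis,
    bin_frames = as.integer(bin_frames),
    bin_seconds = bin_frames / fr,
    window = window,
    frame_rate = fr,
    trial_index = tr$index[sel]
  ), class = "aligned_activity")
}

#' @export
print.aligned_activity <- function(x, ...) {
  d <- dim(x$tensor)
  cat(sprintf(
    "aligned_activity: %d neurons x %d trials x %d bins (%.4f s bins, window [%g, %g] s)\n",
    d[1], d[2], d[3], x$bin_seconds, x$window[1], x$window[2]))
  invisible(x)
}

# Subset an aligned tensor to a set of trial-table indices.
subset_trials <- function(aligned, trial_idx) {
  pos <- match(trial_idx, aligned$trial_index)
  if (anyNA(pos))
    validation_error("requested trials are not present in the aligned tensor")
  out <- aligned
  out$tensor <- aligned$tensor[, pos, , drop = FALSE]
  out$trial_index <- aligned$trial_index[pos]
  out
}

#' Nearest-neighbor matching of standard trials to reverse trials
#'
#' Balances trial counts between a reverse condition and its standard
#' comparison condition by assigning, to each reverse trial in ascending
#' index order, the still-unused eligible standard trial with the smallest
#' absolute trial-index difference; ties break toward the earlier standard
#' trial. The result is a bijection from the reverse subset into the
#' standard pool.
#'
#' @param reverse_idx trial indices of the reverse trials.
#' @param standard_idx trial indices of the eligible standard trials (the
#'   caller restricts these to the comparison's category, e.g. short-delay
#'   standards when comparing against reverse-short trials).
#' @return data.frame with columns `reverse` and `standard`.
#' @export
match_standard_trials <- function(reverse_idx, standard_idx) {
  if (length(standard_idx) < length(reverse_idx))
    validation_error(sprintf(
      "need at least %d standard trials to match %d reverse trials",
      length(reverse_idx), length(reverse_idx)))
  avail <- sort(standard_idx)
  rev_sorted <- sort(reverse_idx)
  chosen <- integer(length(rev_sorted))
  for (i in seq_along(rev_sorted)) {
    j <- which.min(abs(avail - rev_sorted[i]))  # first minimum = earlier trial
    chosen[i] <- avail[j]
    avail <- avail[-j]
  }
  data.frame(reverse = rev_sorted, standard = chosen)
}
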