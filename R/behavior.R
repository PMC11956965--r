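#' Score a single trial
#'
#' Non-match trials are correct iff at least one lick falls in the response
#' window `[odor2_onset, odor2_onset + response_window)` (half-open; a lick
#' at exactly the window end does not count). Match trials are correct iff
#' no lick falls in that window. Licks outside the window are retained in
#' the data but never scored.
#'
#' @param licks numeric vector of lick times (session seconds).
#' @param odor2_onset second-odor onset (seconds).
#' @param is_match whether the trial is a match trial.
#' @param response_window window length in seconds (default 3).
#' @return logical: trial correct.
#' @export
score_trial <- function(licks, odor2_onset, is_match, response_window = 3) {
  inwin <- any(licks >= odor2_onset &
                 licks < odor2_onset + response_window)
  if (is_match) !inwin else inwin
}

#' Score all trials of a session
#'
#' Applies [score_trial()] to every trial and records the first-lick
#' latency (first lick inside the response window minus second-odor onset;
#' `NA` when there is none).
#'
#' @param trials trial table.
#' @param cfg a [task_config()].
#' @return the trial table with `correct` and `first_lick_latency` set.
#' @export
score_trials <- function(trials, cfg) {
  rw <- cfg$response_window
  trials$correct <- vapply(seq_len(nrow(trials)), function(i)
    score_trial(trials$licks[[i]], trials$odor2_onset[i],
                trials$is_match[i], rw), logical(1))
  trials$first_lick_latency <- vapply(seq_len(nrow(trials)), function(i) {
    l <- trials$licks[[i]]
    l <- l[l >= trials$odor2_onset[i] & l < trials$odor2_onset[i] + rw]
    if (length(l)) l[1] - trials$odor2_onset[i] else NA_real_
  }, numeric(1))
  trials
}

#' Summarize behavior by category
#'
#' Accuracy (% correct) and median first-lick latency per trial category
#' (standard/reverse x short/long) and pooled standard/reverse. Latency
#' medians use all trials with a first lick inside the response window
#' (set `correct_only = TRUE` to restrict to correct trials). An empty
#' category is reported with `NA`, never 0.
#'
#' @param trials a scored trial table (see [score_trials()]).
#' @param cfg a [task_config()].
#' @param correct_only restrict latency medians to correct trials.
#' @return data.frame with `category`, `n_trials`, `accuracy_pct`,
#'   `median_latency_ms`.
#' @export
summarize_behavior <- function(trials, cfg, correct_only = FALSE) {
  if (anyNA(trials$correct)) trials <- score_trials(trials, cfg)
  cat_ <- trial_categories(trials, cfg)
  pooled <- ifelse(trials$is_reverse, "reverse", "standard")
  groups <- c(split(seq_len(nrow(trials)), cat_),
              split(seq_len(nrow(trials)), pooled))
  all_cats <- c("standard_short", "standard_long", "reverse_short",
                "reverse_long", "standard", "reverse")
  rows <- lapply(all_cats, function(cc) {
    idx <- groups[[cc]]
    if (is.null(idx) || !length(idx))
      return(data.frame(category = cc, n_trials = 0L,
                        accuracy_pct = NA_real_,
                        median_latency_ms = NA_real_))
    lat_idx <- idx[!is.na(trials$first_lick_latency[idx])]
    if (correct_only) lat_idx <- lat_idx[trials$correct[lat_idx]]
    data.frame(
      category = cc, n_trials = length(idx),
      accuracy_pct = 100 * mean(trials$correct[idx]),
      median_latency_ms = if (length(lat_idx))
        1000 * stats::median(trials$first_lick_latency[lat_idx]) else
          NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Paired comparison of per-session behavioral values
#'
#' Paired t-test across sessions between two matched categories (e.g.
#' standard vs reverse accuracy). Identical pairs give t = 0 and p = 1.
#'
#' @param a,b numeric vectors of per-session values (same length).
#' @return list with `p.value`, `t`, `mean_diff`, `n`.
#' @export
paired_category_test <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 2,
              "need >= 2 paired sessions")
  d <- a - b
  if (all(abs(d - d[1]) < 1e-12)) {
    if (abs(d[1]) < 1e-12)
      return(list(p.value = 1, t = 0, mean_diff = 0, n = length(d)))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(p.value = tt$p.value, t = unname(tt$statistic),
       mean_diff = mean(d), n = length(d))
}

#' Locomotion parameters
#'
#' @param bin_frames frames per locomotion bin (default 5).
#' @param z_floor z-score below which binned locomotion is zeroed
#'   (default 1).
#' @param bout_min_duration minimum running-bout duration in seconds
#'   (default 1; the threshold is closed, so a bout of exactly 1 s counts).
#' @return a list of class `locomotion_params`.
#' @export
locomotion_params <- function(bin_frames = 5, z_floor = 1,
                              bout_min_duration = 1) {
  assert_that(is_count(bin_frames) && bin_frames >= 1 && z_floor > 0 &&
                bout_min_duration > 0,
              "locomotion parameters must be positive", config_error)
  structure(list(bin_frames = as.integer(bin_frames), z_floor = z_floor,
                 bout_min_duration = bout_min_duration),
            class = c("locomotion_params", "list"))
}

#' Bin and z-score a locomotion trace
#'
#' Bins the per-frame trace into `bin_frames`-frame means (partial trailing
#' bin dropped), z-scores the whole binned series, and zeroes values below
#' `z_floor`. A constant trace yields all zeros (zero-variance rule).
#'
#' @param trace per-frame locomotion values.
#' @param frame_rate frames per second.
#' @param params a [locomotion_params()].
#' @return list with `values` (z-binned series), `bin_seconds`, and
#'   `bin_times` (bin-center times in session seconds).
#' @export
locomotion_zbin <- function(trace, frame_rate,
                            params = locomotion_params()) {
  bf <- params$bin_frames
  n_bins <- length(trace) %/% bf
  m <- matrix(trace[seq_len(n_bins * bf)], nrow = bf)
  binned <- colMeans(m)
  sdv <- stats::sd(binned)
  z <- if (is.na(sdv) || sdv <= .Machine$double.eps^0.5)
    rep(0, n_bins) else (binned - mean(binned)) / sdv
  z[z < params$z_floor] <- 0
  list(values = z, bin_seconds = bf / frame_rate,
       bin_times = ((seq_len(n_bins) - 1) * bf + bf / 2) / frame_rate)
}

#' Detect running bouts
#'
#' Maximal runs of consecutive z-binned values above 1 lasting at least
#' `bout_min_duration` seconds (closed threshold). Detection is idempotent
#' and unaffected by appended zero-padding.
#'
#' @param zbinned output of [locomotion_zbin()].
#' @param params a [locomotion_params()].
#' @return data.frame with `start_bin`, `end_bin`, `start_s`, `end_s`,
#'   `duration_s` (possibly zero rows).
#' @export
running_bouts <- function(zbinned, params = locomotion_params()) {
  v <- zbinned$values > params$z_floor
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values &
    r$lengths * zbinned$bin_seconds >= params$bout_min_duration - 1e-9
  bs <- zbinned$bin_seconds
  data.frame(
    start_bin = starts[keep], end_bin = ends[keep],
    start_s = (starts[keep] - 1L) * bs,
    end_s = ends[keep] * bs,
    duration_s = r$lengths[keep] * bs)
}

#' Flag trials with delay-period running
#'
#' A trial is "running" iff any detected bout intersects its delay period
#' (first-odor offset to second-odor onset).
#'
#' @param bouts output of [running_bouts()].
#' @param trials trial table.
#' @param cfg a [task_config()].
#' @return logical vector, one flag per trial.
#' @export
trial_running_flags <- function(bouts, trials, cfg) {
  d0 <- trials$odor1_onset + cfg$odor_duration
  d1 <- trials$odor2_onset
  vapply(seq_len(nrow(trials)), function(i)
    any(bouts$start_s < d1[i] & bouts$end_s > d0[i]), logical(1))
}

#' Drop running trials from an aligned tensor
#'
#' @param aligned an `aligned_activity`.
#' @param flags logical running flags indexed like the session trial table.
#' @return the aligned object restricted to non-running trials (possibly
#'   with zero trials; downstream stages then raise their own
#'   insufficient-trials errors).
#' @export
exclude_running <- function(aligned, flags) {
  keep <- aligned$trial_index[!flags[aligned$trial_index]]
  out <- aligned
  pos <- match(keep, aligned$trial_index)
  out$tensor <- aligned$tensor[, pos, , drop = FALSE]
  out$trial_index <- keep
  out
}
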