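#' Sequence-cell detection parameters
#'
#' Defaults follow the published criterion: the trial-averaged peak must
#' exceed the 95th percentile of 2000 circular shuffles, and the cell must
#' show a >= 2 STD event within 0.5 s of the peak on at least 20% of its
#' preferred trials. Only the period covering the first odor and the delay
#' (3.5 s after the short cue, 6 s after the long cue) is searched.
#'
#' @param n_shuffles number of circular shuffles (default 2000).
#' @param percentile shuffle percentile for the threshold (default 95).
#' @param min_reliability minimum fraction of preferred trials with an
#'   event near the peak (default 0.20).
#' @param peak_window_halfwidth half-width in seconds of the event window
#'   around the peak (default 0.5; the window is closed at its boundaries).
#' @param z_event_threshold activity level (z units) that counts as an
#'   event (default 2).
#' @return a list of class `detection_params`.
#' @export
detection_params <- function(n_shuffles = 2000, percentile = 95,
                             min_reliability = 0.20,
                             peak_window_halfwidth = 0.5,
                             z_event_threshold = 2) {
  assert_that(is_count(n_shuffles) && n_shuffles >= 1,
              "n_shuffles must be a positive count", config_error)
  assert_that(percentile > 0 && percentile < 100,
              "percentile must lie in (0, 100)", config_error)
  assert_that(min_reliability >= 0 && min_reliability <= 1,
              "min_reliability must lie in [0, 1]", config_error)
  assert_that(peak_window_halfwidth > 0 && z_event_threshold > 0,
              "peak window and event threshold must be positive",
              config_error)
  structure(list(n_shuffles = as.integer(n_shuffles), percentile = percentile,
                 min_reliability = min_reliability,
                 peak_window_halfwidth = peak_window_halfwidth,
                 z_event_threshold = z_event_threshold),
            class = c("detection_params", "list"))
}

# Bins of the aligned time axis inside the analysis window [0, win_s).
analysis_bins <- function(time_axis, win_s) {
  which(time_axis >= 0 & time_axis < win_s - 1e-9)
}

#' Preferred trial type of a neuron
#'
#' Standard trials starting with each of the two odors are averaged
#' separately and the odor whose trial-averaged trace has the larger peak
#' within its analysis window (odor + standard delay: 3.5 s or 6 s) is the
#' preferred one. Ties, including fully silent neurons, resolve to the
#' short-cue type (such cells then fail significance downstream).
#'
#' @param aligned an `aligned_activity`.
#' @param trials the session trial table.
#' @param cfg the [task_config()].
#' @param neuron neuron index (row of the tensor).
#' @return list with `preferred` (`"short"` or `"long"`), `preferred_odor`,
#'   and the two candidate peak values.
#' @export
preferred_trial_type <- function(aligned, trials, cfg, neuron) {
  peaks <- vapply(cfg$odor_labels, function(odor) {
    idx <- trials$index[!trials$is_reverse & trials$odor1 == odor]
    pos <- match(idx, aligned$trial_index)
    pos <- pos[!is.na(pos)]
    if (!length(pos)) return(0)
    bins <- analysis_bins(aligned$time_axis, odor_analysis_window(cfg, odor))
    avg <- colMeans(matrix(aligned$tensor[neuron, pos, bins],
                           nrow = length(pos)))
    max(avg)
  }, numeric(1))
  so <- short_odor(cfg)
  lo <- long_odor(cfg)
  pick <- if (peaks[[lo]] > peaks[[so]]) lo else so  # tie -> short
  list(preferred = if (pick == so) "short" else "long",
       preferred_odor = pick,
       peak_short = unname(peaks[[so]]), peak_long = unname(peaks[[lo]]))
}

#' Circular-shuffle significance test for a trial-averaged peak
#'
#' The observed statistic is the maximum of the trial-averaged trace within
#' the analysis window. Each of `n_shuffles` shuffles independently rotates
#' every trial's within-window trace by a uniform random circular offset,
#' re-averages across trials and takes the window maximum; the threshold is
#' the `percentile`-th percentile (linear interpolation) of the shuffle
#' maxima and the test passes iff observed > threshold (strict, so
#' shift-invariant activity such as a constant trace always fails).
#'
#' @param slice matrix, preferred trials x analysis-window bins.
#' @param params a [detection_params()].
#' @param seed optional integer seed (when `NULL`, the current RNG stream
#'   is consumed, which is how [detect_sequence_cells()] keeps one seeded
#'   stream per session).
#' @return list with `observed`, `threshold` and `pass`.
#' @export
circular_shuffle_test <- function(slice, params = detection_params(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  assert_that(is.matrix(slice) && nrow(slice) >= 2,
              "need at least 2 preferred trials")
  n_trials <- nrow(slice)
  n_bins <- ncol(slice)
  observed <- max(colMeans(slice))
  if (all(slice == 0))
    return(list(observed = 0, threshold = 0, pass = FALSE))
  S <- params$n_shuffles
  offs <- matrix(sample.int(n_bins, S * n_trials, replace = TRUE) - 1L,
                 n_trials, S)
  base <- 0:(n_bins - 1L)
  acc <- matrix(0, S, n_bins)
  for (t in seq_len(n_trials)) {
    idx <- (outer(offs[t, ], base, "+") %% n_bins) + 1L
    acc <- acc + matrix(slice[t, idx], S, n_bins)
  }
  maxima <- acc[cbind(seq_len(S), max.col(acc, ties.method = "first"))] /
    n_trials
  threshold <- unname(stats::quantile(maxima, params$percentile / 100,
                                      type = 7))
  list(observed = observed, threshold = threshold,
       pass = observed > threshold)
}

#' Trial reliability of a peak
#'
#' Fraction of preferred trials showing at least one bin at or above the
#' event threshold within `peak_window_halfwidth` seconds of the peak time
#' (closed interval, clipped at the aligned-window edges).
#'
#' @param slice matrix, preferred trials x all aligned bins.
#' @param time_axis bin-center times of `slice`'s columns.
#' @param peak_time peak time in seconds.
#' @param params a [detection_params()].
#' @return a fraction in `[0, 1]`.
#' @export
reliability_fraction <- function(slice, time_axis, peak_time,
                                 params = detection_params()) {
  hw <- params$peak_window_halfwidth
  cols <- which(abs(time_axis - peak_time) <= hw + 1e-9)
  if (!length(cols)) return(0)
  sub <- slice[, cols, drop = FALSE]
  mean(apply(sub >= params$z_event_threshold, 1L, any))
}

#' Detect odor-specific sequence cells
#'
#' For every neuron: assign the preferred trial type, locate the peak of
#' the trial-averaged trace within the analysis window (earliest bin on
#' ties), test it against the circular-shuffle null, and compute trial
#' reliability. A cell is significant iff the shuffle test passes and
#' reliability meets `min_reliability`. Only standard trials enter
#' detection. One seeded RNG stream is consumed in neuron order so
#' detection is byte-reproducible.
#'
#' @param aligned an `aligned_activity` built on conditioned activity.
#' @param trials the session trial table.
#' @param cfg the [task_config()].
#' @param params a [detection_params()].
#' @param seed integer seed for the shuffle draws.
#' @return data.frame with one row per neuron: `neuron`, `preferred`
#'   (`"short"`/`"long"`), `preferred_odor`, `peak_bin` (index into the
#'   aligned time axis), `peak_time`, `observed_peak`, `shuffle_threshold`,
#'   `reliability`, `sig_shuffle`, `significant`.
#' @export
detect_sequence_cells <- function(aligned, trials, cfg,
                                  params = detection_params(), seed = 1L) {
  set.seed(seed)
  n_neurons <- dim(aligned$tensor)[1]
  rows <- vector("list", n_neurons)
  win_cache <- list()
  for (odor in cfg$odor_labels) {
    idx <- trials$index[!trials$is_reverse & trials$odor1 == odor]
    pos <- match(idx, aligned$trial_index)
    win_cache[[odor]] <- list(
      pos = pos[!is.na(pos)],
      bins = analysis_bins(aligned$time_axis,
                           odor_analysis_window(cfg, odor)))
  }
  for (nr in seq_len(n_neurons)) {
    pref <- preferred_trial_type(aligned, trials, cfg, nr)
    wc <- win_cache[[pref$preferred_odor]]
    slice_win <- matrix(aligned$tensor[nr, wc$pos, wc$bins],
                        nrow = length(wc$pos))
    avg <- colMeans(slice_win)
    pk <- which.max(avg)  # earliest bin on ties
    peak_bin <- wc$bins[pk]
    peak_time <- aligned$time_axis[peak_bin]
    sh <- circular_shuffle_test(slice_win, params)
    slice_all <- matrix(aligned$tensor[nr, wc$pos, ],
                        nrow = length(wc$pos))
    rel <- reliability_fraction(slice_all, aligned$time_axis, peak_time,
                                params)
    rows[[nr]] <- data.frame(
      neuron = nr, preferred = pref$preferred,
      preferred_odor = pref$preferred_odor,
      peak_bin = peak_bin, peak_time = peak_time,
      observed_peak = sh$observed, shuffle_threshold = sh$threshold,
      reliability = rel, sig_shuffle = sh$pass,
      significant = sh$pass && rel >= params$min_reliability,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalized, peak-sorted sequence heatmap
#'
#' Rows are the trial-averaged traces of the significant cells of one
#' sequence, each normalized to peak 1 and sorted ascending by peak bin on
#' the preferred trials. The same row order can be reused to render other
#' trial types by passing their trial indices.
#'
#' @param aligned an `aligned_activity`.
#' @param trials the trial table.
#' @param stats output of [detect_sequence_cells()].
#' @param sequence `"short"` or `"long"`.
#' @param trial_idx trials to average (default: the sequence's preferred
#'   standard trials).
#' @param order optional explicit row order (neuron ids) to reuse.
#' @return matrix cells x bins with attributes `neurons` (row order) and
#'   `time_axis`.
#' @export
sequence_heatmap <- function(aligned, trials, stats, sequence = "short",
                             trial_idx = NULL, order = NULL) {
  cells <- stats[stats$significant & stats$preferred == sequence, ,
                 drop = FALSE]
  if (is.null(order)) {
    cells <- cells[order(cells$peak_bin, cells$neuron), , drop = FALSE]
    order <- cells$neuron
  }
  if (is.null(trial_idx)) {
    odor <- cells$preferred_odor[1]
    trial_idx <- trials$index[!trials$is_reverse & trials$odor1 == odor]
  }
  pos <- match(trial_idx, aligned$trial_index)
  pos <- pos[!is.na(pos)]
  m <- t(vapply(order, function(nr) {
    avg <- colMeans(matrix(aligned$tensor[nr, pos, ], nrow = length(pos)))
    pk <- max(avg)
    if (pk > 0) avg / pk else avg
  }, numeric(dim(aligned$tensor)[3])))
  attr(m, "neurons") <- order
  attr(m, "time_axis") <- aligned$time_axis
  m
}

#' Compare peak-time distributions between sequences
#'
#' Two-sample Kolmogorov-Smirnov test on pooled significant peak times,
#' restricted to a common window (default the first 3.5 s, the shared
#' odor + short-delay period).
#'
#' @param short_peaks,long_peaks peak times in seconds.
#' @param window two-element window; peaks in `[window[1], window[2])` are
#'   kept.
#' @return list with `statistic`, `p.value`, `n_short`, `n_long`.
#' @export
compare_peak_distributions <- function(short_peaks, long_peaks,
                                       window = c(0, 3.5)) {
  s <- short_peaks[short_peaks >= window[1] & short_peaks < window[2]]
  l <- long_peaks[long_peaks >= window[1] & long_peaks < window[2]]
  assert_that(length(s) >= 1 && length(l) >= 1,
              "need peaks in the window for both sequences")
  if (identical(sort(s), sort(l)))
    return(list(statistic = 0, p.value = 1,
                n_short = length(s), n_long = length(l)))
  ks <- suppressWarnings(stats::ks.test(s, l))
  list(statistic = unname(ks$statistic), p.value = ks$p.value,
       n_short = length(s), n_long = length(l))
}

#' Per-session binned peak fractions and paired tests
#'
#' For each session, the significant cells of each sequence with a peak
#' inside the window are binned into 0.5-s bins; fractions use the
#' windowed cell count as denominator (so they sum to 1 per session and
#' sequence). Each bin is then compared between sequences with a paired
#' t-test across sessions, Benjamini-Hochberg-adjusted across bins.
#'
#' @param stats_list list of [detect_sequence_cells()] outputs, one per
#'   session/animal (at least 2).
#' @param bin bin width in seconds (default 0.5).
#' @param window window in seconds (default `c(0, 3.5)`).
#' @return list with `fractions` (array session x sequence x bin),
#'   `bin_starts`, and `tests` (data.frame `bin_start`, `mean_short`,
#'   `mean_long`, `p`, `p_adj`).
#' @export
binned_peak_fractions <- function(stats_list, bin = 0.5,
                                  window = c(0, 3.5)) {
  assert_that(is.list(stats_list) && length(stats_list) >= 2,
              "need at least 2 sessions for the paired comparison")
  starts <- seq(window[1], window[2] - bin / 2, by = bin)
  n_bins <- length(starts)
  frac <- array(NA_real_, dim = c(length(stats_list), 2, n_bins),
                dimnames = list(NULL, c("short", "long"), NULL))
  for (s in seq_along(stats_list)) {
    st <- stats_list[[s]]
    for (sq in c("short", "long")) {
      pk <- st$peak_time[st$significant & st$preferred == sq]
      pk <- pk[pk >= window[1] & pk < window[2]]
      if (!length(pk)) next
      b <- pmin(floor((pk - window[1]) / bin) + 1L, n_bins)
      frac[s, sq, ] <- tabulate(b, n_bins) / length(pk)
    }
  }
  p <- vapply(seq_len(n_bins), function(b) {
    d <- frac[, "short", b] - frac[, "long", b]
    d <- d[!is.na(d)]
    if (length(d) < 2) return(NA_real_)
    if (all(abs(d - d[1]) < 1e-12)) {
      if (abs(d[1]) < 1e-12) return(1)  # identical fractions: no evidence
      return(NA_real_)
    }
    stats::t.test(d)$p.value
  }, numeric(1))
  tests <- data.frame(
    bin_start = starts,
    mean_short = apply(frac[, "short", , drop = FALSE], 3, mean,
                       na.rm = TRUE),
    mean_long = apply(frac[, "long", , drop = FALSE], 3, mean, na.rm = TRUE),
    p = p,
    p_adj = stats::p.adjust(p, "BH"))
  list(fractions = frac, bin_starts = starts, tests = tests)
}
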