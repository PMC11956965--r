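#' Parameters for the synthetic session generator
#'
#' The generator emulates the statistical structure the downstream analyses
#' assume: a blocked pseudorandom trial schedule, odor-specific sequence
#' cells tiling the odor + delay period with tunable trial reliability, an
#' optional over-representation of peak times in the last 0.5 s of the short
#' delay, second-odor-evoked cells, background-only noise cells, lick
#' behavior with plantable accuracy/latency effects, and sparse locomotion
#' bouts. Defaults are the published session scale: ~400 active neurons of
#' which ~14% are sequence cells, accuracies of 87.5/86.5/86.8/80.8% for
#' standard-short/standard-long/reverse-short/reverse-long trials, lick
#' latency 563 +/- 243 ms with a +21 ms shift on reverse trials.
#'
#' @param n_sequence_cells planted sequence cells per cue odor (default 28);
#'   a length-2 vector gives separate counts for the short-cue and long-cue
#'   sequences (in that order), e.g. to plant denser short-delay tiling.
#' @param n_second_odor_cells cells per odor responding to that odor when it
#'   arrives as the second odor (default 8), so odor-information curves show
#'   a second peak at second-odor time.
#' @param n_noise_cells cells emitting background activity only (default 328).
#' @param overrep_weight extra probability mass placed on field centers in
#'   the last 0.5 s of the short delay for short-cue cells (default 0.1);
#'   with weight `w`, a short-cue field center is drawn uniformly from the
#'   last 0.5 s with probability `w` and uniformly over the whole
#'   odor + short delay otherwise.
#' @param field_width Gaussian SD of a planted field, seconds (default 0.25).
#' @param amplitude transient amplitude in raw activity units (default 6).
#' @param reliability probability that a preferred trial expresses the field
#'   (default 0.6).
#' @param background_rate expected spurious events per second for every cell
#'   (default 0.05).
#' @param noise_sd SD of the half-normal additive noise floor (default 0.3).
#' @param behavior list: `accuracy` (named per category), `latency_mean`,
#'   `latency_sd`, `reverse_latency_shift`, all in seconds.
#' @param locomotion list: `bout_prob` (per-trial probability of a running
#'   bout during the delay), `bout_duration` range in seconds (>= 1 s),
#'   `bout_amp`, `twitch_amp`, `twitch_duration` (flinches at odor onsets),
#'   `noise_sd`.
#' @return a list of class `generator_params`.
#' @export
generator_params <- function(n_sequence_cells = 28,
                             n_second_odor_cells = 8,
                             n_noise_cells = 328,
                             overrep_weight = 0.1,
                             field_width = 0.25,
                             amplitude = 6,
                             reliability = 0.6,
                             background_rate = 0.05,
                             noise_sd = 0.3,
                             behavior = list(),
                             locomotion = list()) {
  beh <- utils::modifyList(list(
    accuracy = c(standard_short = 0.8750, standard_long = 0.8649,
                 reverse_short = 0.8680, reverse_long = 0.8075),
    latency_mean = 0.563,
    latency_sd = 0.243,
    reverse_latency_shift = 0.021
  ), behavior)
  loco <- utils::modifyList(list(
    bout_prob = 0.15,
    bout_duration = c(1, 2.5),
    bout_amp = 1,
    twitch_amp = 0.3,
    twitch_duration = 0.2,
    noise_sd = 0.05
  ), locomotion)
  p <- list(
    n_sequence_cells = n_sequence_cells,
    n_second_odor_cells = n_second_odor_cells,
    n_noise_cells = n_noise_cells,
    overrep_weight = overrep_weight,
    field_width = field_width,
    amplitude = amplitude,
    reliability = reliability,
    background_rate = background_rate,
    noise_sd = noise_sd,
    behavior = beh,
    locomotion = loco
  )
  with(p, {
    assert_that(all(vapply(as.list(c(n_sequence_cells, n_second_odor_cells,
                                     n_noise_cells)), is_count, logical(1))),
                "cell counts must be nonnegative integers", config_error)
    assert_that(overrep_weight >= 0 && overrep_weight <= 1 &&
                  reliability >= 0 && reliability <= 1 &&
                  all(beh$accuracy >= 0 & beh$accuracy <= 1) &&
                  loco$bout_prob >= 0 && loco$bout_prob <= 1,
                "probabilities must lie in [0, 1]", config_error)
    assert_that(field_width > 0 && amplitude >= 0 && noise_sd >= 0 &&
                  background_rate >= 0,
                "field_width must be > 0; amplitudes/rates nonnegative",
                config_error)
  })
  structure(p, class = c("generator_params", "list"))
}

#' Generate a trial schedule
#'
#' Builds `n_blocks x trials_per_block` trials. Within each block the four
#' odor pairs (AA, AB, BA, BB) appear equally often in pseudorandom order
#' (`trials_per_block` must be divisible by 4). Exactly
#' `round(reverse_fraction * n_trials)` trials are flagged reverse —
#' enforced by count, not sampled per trial — and distributed pseudorandomly
#' across the session. Delays follow the cue-delay map and are swapped on
#' reverse trials. Onsets are laid out with the configured fixed ITI.
#'
#' @param cfg a [task_config()].
#' @param seed optional integer; when given, the schedule is a deterministic
#'   function of `(cfg, seed)`.
#' @return a trial table (data.frame with list column `licks`, initially
#'   empty; `rewarded`, `correct`, `first_lick_latency` initially `NA`).
#' @export
generate_trials <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$trials_per_block %% 4L != 0L)
    config_error("trials_per_block must be divisible by 4")
  labs <- cfg$odor_labels
  pairs <- expand.grid(odor1 = labs, odor2 = labs,
                       stringsAsFactors = FALSE)[, c("odor1", "odor2")]
  per <- cfg$trials_per_block %/% 4L
  blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
    idx <- sample(rep(seq_len(4L), per))
    cbind(pairs[idx, , drop = FALSE], block = b)
  })
  tr <- do.call(rbind, blocks)
  n <- nrow(tr)
  rownames(tr) <- NULL
  tr$index <- seq_len(n)
  n_rev <- round(cfg$reverse_fraction * n)
  tr$is_reverse <- FALSE
  if (n_rev > 0) tr$is_reverse[sample.int(n, n_rev)] <- TRUE
  std_delay <- unname(cfg$delay_map[tr$odor1])
  # the swapped contingency: the other of the two delay durations
  tr$delay <- ifelse(tr$is_reverse,
                     min(cfg$delay_map) + max(cfg$delay_map) - std_delay,
                     std_delay)
  tr$is_match <- tr$odor1 == tr$odor2
  trial_len <- cfg$odor_duration + tr$delay + cfg$odor_duration +
    cfg$response_window
  tr$odor1_onset <- 5 + cumsum(c(0, (trial_len + cfg$iti)[-n]))
  tr$odor2_onset <- tr$odor1_onset + cfg$odor_duration + tr$delay
  tr$licks <- replicate(n, numeric(0), simplify = FALSE)
  tr$rewarded <- NA
  tr$correct <- NA
  tr$first_lick_latency <- NA_real_
  tr[, c("index", "block", "odor1", "odor2", "delay", "is_reverse",
         "is_match", "odor1_onset", "odor2_onset", "licks", "rewarded",
         "correct", "first_lick_latency")]
}

# Draw the planted-cell table (ground truth) for one session.
draw_planted_cells <- function(cfg, params) {
  rows <- list()
  n_seq <- rep_len(params$n_sequence_cells, 2)  # (short-cue, long-cue)
  for (odor in cfg$odor_labels) {
    n <- if (odor == short_odor(cfg)) n_seq[1] else n_seq[2]
    if (n == 0) next
    win <- odor_analysis_window(cfg, odor)
    center <- stats::runif(n, 0, win)
    if (odor == short_odor(cfg) && params$overrep_weight > 0) {
      bump <- stats::runif(n) < params$overrep_weight
      center[bump] <- stats::runif(sum(bump), win - 0.5, win)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      preferred_odor = odor, role = "sequence", center_s = center,
      width_s = params$field_width, amplitude = params$amplitude,
      reliability = params$reliability, stringsAsFactors = FALSE)
  }
  for (odor in cfg$odor_labels) {
    n <- params$n_second_odor_cells
    if (n == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      preferred_odor = odor, role = "odor2",
      center_s = stats::runif(n, 0, cfg$odor_duration),
      width_s = params$field_width, amplitude = params$amplitude,
      reliability = params$reliability, stringsAsFactors = FALSE)
  }
  if (params$n_noise_cells > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      preferred_odor = NA_character_, role = "noise",
      center_s = NA_real_, width_s = NA_real_, amplitude = NA_real_,
      reliability = NA_real_, stringsAsFactors = FALSE)[
        rep(1L, params$n_noise_cells), , drop = FALSE]
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth$neuron <- seq_len(nrow(truth))
  truth$is_odor_cell <- !is.na(truth$center_s) & truth$role == "sequence" &
    truth$center_s <= cfg$odor_duration
  truth[, c("neuron", "preferred_odor", "role", "center_s", "width_s",
            "amplitude", "reliability", "is_odor_cell")]
}

session_frame_count <- function(cfg, trials) {
  # cover both the response window of the last trial and the widest
  # alignment window used downstream ([-2, 11] s around first-odor onset)
  last_end <- max(max(trials$odor2_onset) + cfg$odor_duration +
                    cfg$response_window,
                  max(trials$odor1_onset) + 11.5) + 2
  as.integer(ceiling(last_end * cfg$frame_rate))
}

#' Generate planted neural activity
#'
#' Emits a "deconvolved-like" nonnegative activity matrix. Each planted
#' sequence cell fires, on each trial whose first odor is its preferred
#' odor, with probability `reliability`, a Gaussian-profile transient
#' centered at its field center; transients are clipped at second-odor
#' onset, so on reverse trials with a shortened delay late fields are
#' truncated. Second-odor cells respond (with the same reliability) when
#' their odor arrives as the second odor. Every cell additionally receives
#' sparse Poisson background impulses and half-normal additive noise; noise
#' cells receive background only. Ground truth is returned alongside.
#'
#' @param cfg a [task_config()].
#' @param trials a trial table from [generate_trials()].
#' @param params a [generator_params()].
#' @param seed optional integer seed.
#' @return list with `activity` (neurons x frames) and `truth` (planted-cell
#'   table: neuron, preferred_odor, role, center_s, width_s, amplitude,
#'   reliability, is_odor_cell).
#' @export
generate_neurons <- function(cfg, trials, params = generator_params(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- draw_planted_cells(cfg, params)
  max_center <- max(c(0, truth$center_s[truth$role == "sequence"]), na.rm = TRUE)
  if (max_center > cfg$odor_duration + max(cfg$delay_map) + 1e-9)
    config_error("planted field center beyond the alignment window")
  fr <- cfg$frame_rate
  n_frames <- session_frame_count(cfg, trials)
  n_cells <- nrow(truth)
  act <- matrix(abs(stats::rnorm(n_cells * n_frames, 0, params$noise_sd)),
                n_cells, n_frames)
  frame_time <- (seq_len(n_frames) - 0.5) / fr  # frame-center times

  add_transient <- function(row, center_abs, clip_end) {
    cell <- truth$neuron[row]
    w <- truth$width_s[row]
    lo <- max(center_abs - 4 * w, 0)
    hi <- min(center_abs + 4 * w, clip_end)
    if (hi <= lo) return(invisible())
    f0 <- max(1L, as.integer(floor(lo * fr)) + 1L)
    f1 <- min(n_frames, as.integer(ceiling(hi * fr)))
    if (f1 < f0) return(invisible())
    idx <- f0:f1
    prof <- truth$amplitude[row] *
      exp(-(frame_time[idx] - center_abs)^2 / (2 * w^2))
    act[cell, idx] <<- act[cell, idx] + prof
    invisible()
  }

  planted <- which(truth$role %in% c("sequence", "odor2"))
  for (row in planted) {
    odor <- truth$preferred_odor[row]
    rel <- truth$reliability[row]
    if (truth$role[row] == "sequence") {
      pref <- which(trials$odor1 == odor)
      fire <- pref[stats::runif(length(pref)) < rel]
      for (t in fire)
        add_transient(row, trials$odor1_onset[t] + truth$center_s[row],
                      clip_end = trials$odor2_onset[t])
    } else {
      pref <- which(trials$odor2 == odor)
      fire <- pref[stats::runif(length(pref)) < rel]
      for (t in fire)
        add_transient(row, trials$odor2_onset[t] + truth$center_s[row],
                      clip_end = trials$odor2_onset[t] + cfg$odor_duration +
                        0.5)
    }
  }

  # sparse trial-independent background impulses for every cell
  if (params$background_rate > 0) {
    lam <- params$background_rate * n_frames / fr
    n_ev <- stats::rpois(n_cells, lam)
    for (cell in which(n_ev > 0)) {
      at <- sample.int(n_frames, n_ev[cell], replace = TRUE)
      act[cell, at] <- act[cell, at] + stats::runif(n_ev[cell], 2, 6)
    }
  }
  list(activity = act, truth = truth)
}

#' Generate lick behavior and trial outcomes
#'
#' Draws each trial's correctness from its category's accuracy probability,
#' then constructs licks consistent with the outcome: on response trials
#' (correct non-match, or incorrect match) a first lick is placed at
#' second-odor onset plus a latency drawn from a normal distribution
#' (shifted on reverse trials), truncated into the response window with a
#' warning if any mass falls outside; two follow-up licks are appended
#' inside the window. Rewards follow licks on non-match trials.
#'
#' @param trials trial table.
#' @param cfg a [task_config()].
#' @param params a [generator_params()] (only `$behavior` is used).
#' @param seed optional integer seed.
#' @return the trial table with `licks`, `rewarded`, `correct` and
#'   `first_lick_latency` filled in.
#' @export
generate_behavior <- function(trials, cfg, params = generator_params(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  beh <- params$behavior
  cat_ <- trial_categories(trials, cfg)
  acc <- beh$accuracy[cat_]
  if (anyNA(acc))
    config_error(paste("behavior accuracy missing for category:",
                       paste(unique(cat_[is.na(acc)]), collapse = ", ")))
  n <- nrow(trials)
  correct <- stats::runif(n) < acc
  licked <- ifelse(trials$is_match, !correct, correct)
  lat <- stats::rnorm(n, beh$latency_mean +
                        ifelse(trials$is_reverse,
                               beh$reverse_latency_shift, 0),
                      beh$latency_sd)
  out_of_window <- licked & (lat < 0 | lat >= cfg$response_window)
  if (any(out_of_window)) {
    warning(sprintf("%d lick latencies fell outside the response window%s",
                    sum(out_of_window), "; truncated"), call. = FALSE)
    lat <- pmin(pmax(lat, 0.01), cfg$response_window - 0.01)
  }
  trials$correct <- correct
  trials$rewarded <- licked & !trials$is_match
  trials$first_lick_latency <- ifelse(licked, lat, NA_real_)
  trials$licks <- lapply(seq_len(n), function(i) {
    if (!licked[i]) return(numeric(0))
    first <- trials$odor2_onset[i] + lat[i]
    follow <- first + c(0.15, 0.3)
    keep <- follow < trials$odor2_onset[i] + cfg$response_window
    c(first, follow[keep])
  })
  trials
}

#' Generate a locomotion trace
#'
#' Low-amplitude half-normal noise everywhere, a brief "twitch" at every
#' odor onset, and, with per-trial probability `bout_prob`, one running bout
#' of at least 1 s placed inside the delay period.
#'
#' @param trials trial table.
#' @param cfg a [task_config()].
#' @param params a [generator_params()] (only `$locomotion` is used).
#' @param n_frames trace length; defaults to the session frame count.
#' @param seed optional integer seed.
#' @return list with `trace` (numeric, per frame) and `bout_trials`
#'   (indices of trials that received a planted delay bout).
#' @export
generate_locomotion <- function(trials, cfg, params = generator_params(),
                                n_frames = session_frame_count(cfg, trials),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loco <- params$locomotion
  fr <- cfg$frame_rate
  trace <- abs(stats::rnorm(n_frames, 0, loco$noise_sd))
  stamp <- function(t0, dur, amp) {
    f0 <- max(1L, as.integer(floor(t0 * fr)) + 1L)
    f1 <- min(n_frames, as.integer(ceiling((t0 + dur) * fr)))
    if (f1 >= f0) trace[f0:f1] <<- trace[f0:f1] + amp
    invisible()
  }
  for (i in seq_len(nrow(trials))) {
    stamp(trials$odor1_onset[i], loco$twitch_duration, loco$twitch_amp)
    stamp(trials$odor2_onset[i], loco$twitch_duration, loco$twitch_amp)
  }
  bout_trials <- integer(0)
  if (loco$bout_prob > 0) {
    hit <- which(stats::runif(nrow(trials)) < loco$bout_prob)
    for (i in hit) {
      delay_start <- trials$odor1_onset[i] + cfg$odor_duration
      delay_len <- trials$delay[i]
      dur <- stats::runif(1, loco$bout_duration[1],
                          min(loco$bout_duration[2], delay_len))
      t0 <- delay_start + stats::runif(1, 0, max(delay_len - dur, 0))
      stamp(t0, dur, loco$bout_amp)
    }
    bout_trials <- hit
  }
  list(trace = trace, bout_trials = bout_trials)
}

#' Generate a complete synthetic session
#'
#' Runs [generate_trials()], [generate_behavior()], [generate_neurons()] and
#' [generate_locomotion()] under a single seed and assembles a validated
#' [session_recording()] plus its ground truth. Identical `(cfg, params,
#' seed)` yield identical sessions.
#'
#' @param cfg a [task_config()].
#' @param params a [generator_params()].
#' @param seed integer seed (required: sessions are meant to be reproducible).
#' @param metadata metadata list forwarded to the recording.
#' @return list with `recording` (a `session_recording`), `truth` (the
#'   planted-cell table) and `bout_trials`.
#' @export
generate_session <- function(cfg = task_config(),
                             params = generator_params(),
                             seed,
                             metadata = list()) {
  set.seed(seed)
  trials <- generate_trials(cfg)
  trials <- generate_behavior(trials, cfg, params)
  neur <- generate_neurons(cfg, trials, params)
  loco <- generate_locomotion(trials, cfg, params,
                              n_frames = ncol(neur$activity))
  rec <- session_recording(neur$activity, trials, loco$trace, cfg,
                           metadata = metadata)
  list(recording = rec, truth = neur$truth, bout_trials = loco$bout_trials)
}
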