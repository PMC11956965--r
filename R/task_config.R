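#' Task configuration for the cued-delay non-match-to-sample task
#'
#' Describes one session of the differential delayed-non-match-to-sample
#' (dDNMS) task: two odors are used as cues, the identity of the first odor
#' determines the delay before the second odor (2.5 s after the "short" cue,
#' 5.0 s after the "long" cue), and a fraction of trials are "reverse" trials
#' on which the cue-delay contingency is swapped. Animals respond by licking
#' during a response window that starts at second-odor onset; non-match
#' trials are rewarded.
#'
#' @param odor_labels character pair naming the two odors (default
#'   `c("A", "B")`).
#' @param odor_duration odor presentation length in seconds (default 1).
#' @param delay_short,delay_long the two delay durations in seconds
#'   (defaults 2.5 and 5.0). They must be strictly positive and distinct.
#' @param counterbalance if `FALSE` (default) the first odor label cues the
#'   short delay; if `TRUE` the mapping is swapped (half the animals are
#'   trained the opposite way).
#' @param reverse_fraction fraction of trials with the contingency reversed
#'   (default 0.2); must lie in `[0, 1)`.
#' @param n_blocks,trials_per_block session structure (defaults 7 blocks of
#'   20 trials). `trials_per_block` must be divisible by 4 so the four odor
#'   pairs can appear equally often within a block.
#' @param response_window response window length in seconds, starting at
#'   second-odor onset (default 3).
#' @param frame_rate imaging frame rate in Hz (default 30.9).
#' @param iti inter-trial interval in seconds between the end of one trial's
#'   response window and the next first-odor onset (default 10; the source
#'   data do not pin this down, so it is configurable).
#'
#' @return an object of class `task_config`: a list with the fields above
#'   plus `delay_map`, a named numeric vector mapping each odor label to its
#'   standard (non-reverse) delay.
#' @export
task_config <- function(odor_labels = c("A", "B"),
                        odor_duration = 1,
                        delay_short = 2.5,
                        delay_long = 5,
                        counterbalance = FALSE,
                        reverse_fraction = 0.2,
                        n_blocks = 7,
                        trials_per_block = 20,
                        response_window = 3,
                        frame_rate = 30.9,
                        iti = 10) {
  assert_that(is.character(odor_labels) && length(odor_labels) == 2L &&
                !anyDuplicated(odor_labels),
              "odor_labels must be two distinct labels", config_error)
  assert_that(is_scalar_num(odor_duration) && odor_duration > 0,
              "odor_duration must be > 0", config_error)
  assert_that(is_scalar_num(delay_short) && is_scalar_num(delay_long) &&
                delay_short > 0 && delay_long > 0 && delay_short != delay_long,
              "delays must be strictly positive and distinct", config_error)
  assert_that(is_scalar_num(reverse_fraction) &&
                reverse_fraction >= 0 && reverse_fraction < 1,
              "reverse_fraction must lie in [0, 1)", config_error)
  assert_that(is_count(n_blocks) && n_blocks > 0 &&
                is_count(trials_per_block) && trials_per_block > 0,
              "n_blocks and trials_per_block must be positive counts",
              config_error)
  assert_that(is_scalar_num(response_window) && response_window > 0,
              "response_window must be > 0", config_error)
  assert_that(is_scalar_num(frame_rate) && frame_rate > 0,
              "frame_rate must be > 0", config_error)
  assert_that(is_scalar_num(iti) && iti >= 0, "iti must be >= 0", config_error)

  delay_map <- if (counterbalance) c(delay_long, delay_short) else
    c(delay_short, delay_long)
  names(delay_map) <- odor_labels

  structure(list(
    odor_labels = odor_labels,
    odor_duration = odor_duration,
    delay_map = delay_map,
    reverse_fraction = reverse_fraction,
    n_blocks = n_blocks,
    trials_per_block = trials_per_block,
    response_window = response_window,
    frame_rate = frame_rate,
    counterbalance = counterbalance,
    iti = iti
  ), class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("dDNMS task configuration\n")
  cat(sprintf("  odors: %s (%.1f s), delays: %s\n",
              paste(x$odor_labels, collapse = "/"), x$odor_duration,
              paste(sprintf("%s->%.1fs", names(x$delay_map), x$delay_map),
                    collapse = ", ")))
  cat(sprintf("  %d blocks x %d trials, reverse fraction %.2f\n",
              x$n_blocks, x$trials_per_block, x$reverse_fraction))
  cat(sprintf("  response window %.1f s, frame rate %.2f Hz\n",
              x$response_window, x$frame_rate))
  invisible(x)
}

# Odor whose standard contingency is the short delay.
short_odor <- function(cfg) names(cfg$delay_map)[which.min(cfg$delay_map)]
long_odor  <- function(cfg) names(cfg$delay_map)[which.max(cfg$delay_map)]

# Analysis window (1st odor + standard delay) for a given cue odor, seconds.
odor_analysis_window <- function(cfg, odor) {
  unname(cfg$odor_duration + cfg$delay_map[[odor]])
}

#' Trial categories
#'
#' Classifies each trial as `standard_short`, `standard_long`,
#' `reverse_short` or `reverse_long` by its reverse flag and realized delay
#' duration ("short"/"long" refer to the delay the animal experienced, as in
#' the behavioral comparisons split by delay length).
#'
#' @param trials a trial table (see [generate_trials()]).
#' @param cfg the [task_config()].
#' @return a character vector, one entry per trial.
#' @export
trial_categories <- function(trials, cfg) {
  short <- min(cfg$delay_map)
  len <- ifelse(abs(trials$delay - short) < 1e-9, "short", "long")
  paste0(ifelse(trials$is_reverse, "reverse_", "standard_"), len)
}
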