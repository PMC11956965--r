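# Shared fixtures, all generated in code. Test sessions use a short ITI
# (2 s instead of the 10 s default) purely to cut frame counts; every
# analysis under test is within-trial, so the ITI is not a statistical
# knob. Cell counts are scaled down from the default ~400-neuron session
# for the same reason.

small_cfg <- function(...) task_config(iti = 2, ...)

small_params <- function(n_sequence_cells = 12, n_second_odor_cells = 4,
                         n_noise_cells = 30, ...) {
  generator_params(n_sequence_cells = n_sequence_cells,
                   n_second_odor_cells = n_second_odor_cells,
                   n_noise_cells = n_noise_cells, ...)
}

# One small conditioned + aligned session, cached per test run.
cached_session <- local({
  cache <- NULL
  function(seed = 42) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    ses <- suppressWarnings(
      generate_session(small_cfg(), small_params(), seed = seed))
    rec <- ses$recording
    rec$activity <- condition_signal(rec$activity)
    cache <<- list(seed = seed, rec = rec, truth = ses$truth,
                   aligned = align(rec), cfg = rec$cfg,
                   bout_trials = ses$bout_trials)
    cache
  }
})

# Hand-built aligned_activity object for constructed-tensor tests.
make_aligned <- function(tensor, window = c(-2, 11), bin_frames = 5,
                         frame_rate = 30.9,
                         trial_index = seq_len(dim(tensor)[2])) {
  n_bins <- dim(tensor)[3]
  structure(list(
    tensor = tensor,
    time_axis = window[1] + ((seq_len(n_bins) - 1) * bin_frames +
                               bin_frames / 2) / frame_rate,
    bin_frames = as.integer(bin_frames),
    bin_seconds = bin_frames / frame_rate,
    window = window,
    frame_rate = frame_rate,
    trial_index = trial_index
  ), class = "aligned_activity")
}

standard_trials_of <- function(trials, odor) {
  trials$index[!trials$is_reverse & trials$odor1 == odor]
}
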