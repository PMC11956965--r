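#' Odor-information parameters
#'
#' @param n_levels number of activity levels for discretization (default 20).
#' @param baseline_time time of the baseline bin in seconds relative to
#'   first-odor onset (default -1.5).
#' @param bin_range displayed/analyzed bin range in seconds (default
#'   `c(-1, 11)`; the baseline bin at -1.5 s sits outside this display
#'   range by design and is kept as-is).
#' @return a list of class `info_params`.
#' @export
info_params <- function(n_levels = 20, baseline_time = -1.5,
                        bin_range = c(-1, 11)) {
  assert_that(is_count(n_levels) && n_levels >= 2,
              "n_levels must be an integer >= 2", config_error)
  assert_that(baseline_time < 0, "baseline_time must precede odor onset",
              config_error)
  structure(list(n_levels = as.integer(n_levels),
                 baseline_time = baseline_time, bin_range = bin_range),
            class = c("info_params", "list"))
}

#' Discretize activity into uniform levels
#'
#' Per neuron, activity is mapped to integer levels `0 .. n_levels-1` by a
#' uniform partition of `[0, max]` where `max` is that neuron's maximum
#' over the whole tensor: `level = min(floor(v / max * n_levels),
#' n_levels - 1)`, so the maximum maps to the top level and an all-zero
#' neuron stays at level 0.
#'
#' @param aligned an `aligned_activity`.
#' @param n_levels number of levels (default 20).
#' @return the aligned object with an integer tensor and an extra field
#'   `n_levels`.
#' @export
discretize_activity <- function(aligned, n_levels = 20) {
  x <- aligned$tensor
  mx <- apply(x, 1, max)
  out <- array(0L, dim = dim(x))
  pos <- which(mx > 0)
  for (nr in pos) {
    lev <- floor(x[nr, , ] / mx[nr] * n_levels)
    out[nr, , ] <- pmin(lev, n_levels - 1L)
  }
  aligned$tensor <- out
  aligned$n_levels <- as.integer(n_levels)
  aligned
}

#' Plug-in mutual information of a contingency table
#'
#' `MI = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )` with empirical
#' plug-in probabilities and the convention `0 log 0 = 0`.
#'
#' @param counts a nonnegative matrix of joint counts.
#' @return mutual information in bits.
#' @export
mutual_information <- function(counts) {
  N <- sum(counts)
  assert_that(N > 0, "counts must not be all zero")
  p <- counts / N
  px <- rowSums(p)
  py <- colSums(p)
  t <- p * log2(p / outer(px, py))
  sum(t[p > 0])
}

#' Per-bin odor mutual information
#'
#' For each neuron and each target time bin in the range, the joint
#' distribution over trials of (bin identity: baseline vs target,
#' discretized activity level) is tabulated and its plug-in mutual
#' information computed; MI is then averaged across neurons per bin. The
#' bin-identity variable is binary, so MI lies in `[0, 1]` bit. When a
#' reverse condition is compared against a standard one, balance trial
#' counts first with [match_standard_trials()] and pass the matched
#' indices here.
#'
#' @param disc a discretized `aligned_activity` from [discretize_activity()].
#' @param trial_idx trial-table indices of the condition's trials (>= 2).
#' @param params an [info_params()].
#' @return data.frame with `bin_time` and `mi_bits` (mean across neurons).
#' @export
odor_information <- function(disc, trial_idx, params = info_params()) {
  assert_that(length(trial_idx) >= 2, "need at least 2 trials")
  sub <- subset_trials(disc, trial_idx)
  ta <- sub$time_axis
  L <- sub$n_levels %||% (max(sub$tensor) + 1L)
  base_bin <- which.min(abs(ta - params$baseline_time))
  targets <- which(ta >= params$bin_range[1] & ta <= params$bin_range[2])
  n_neurons <- dim(sub$tensor)[1]
  n_trials <- dim(sub$tensor)[2]
  mi <- vapply(targets, function(tb) {
    vals <- vapply(seq_len(n_neurons), function(nr) {
      xb <- sub$tensor[nr, , base_bin]
      xt <- sub$tensor[nr, , tb]
      counts <- rbind(tabulate(xb + 1L, L), tabulate(xt + 1L, L))
      mutual_information(counts)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  data.frame(bin_time = ta[targets], mi_bits = mi)
}
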