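#' Condition-averaged population trajectory
#'
#' Mean across trials of one condition, restricted to a neuron subset (by
#' default all neurons). The neuron subset is usually the significant
#' sequence cells preferring the condition's first odor: short-trial cells
#' for cued-short conditions (standard-short and reverse-long), long-trial
#' cells for cued-long conditions.
#'
#' @param aligned an `aligned_activity`.
#' @param trial_idx trial-table indices to average.
#' @param neurons neuron indices (default all).
#' @return matrix neurons x bins.
#' @export
condition_mean <- function(aligned, trial_idx, neurons = NULL) {
  sub <- subset_trials(aligned, trial_idx)
  neurons <- neurons %||% seq_len(dim(sub$tensor)[1])
  m <- apply(sub$tensor[neurons, , , drop = FALSE], c(1, 3), mean)
  matrix(m, nrow = length(neurons))
}

#' Baseline population vector
#'
#' Per-neuron mean of the condition-averaged trajectory over the baseline
#' bins (default the 2 s preceding first-odor onset).
#'
#' @param traj matrix neurons x bins (a condition mean).
#' @param time_axis bin-center times of the trajectory columns.
#' @param window baseline window (default `c(-2, 0)`; bins with centers in
#'   `[window[1], window[2])` are used).
#' @return numeric vector, one value per neuron.
#' @export
baseline_point <- function(traj, time_axis, window = c(-2, 0)) {
  cols <- which(time_axis >= window[1] & time_axis < window[2])
  assert_that(length(cols) >= 1, "no bins inside the baseline window")
  rowMeans(traj[, cols, drop = FALSE])
}

#' Distance of the population trajectory from baseline
#'
#' Per time bin, the Euclidean distance in full dimensional space between
#' the population vector and the baseline point, normalized by the square
#' root of the number of cells so values are comparable across sessions
#' with different counts of significant neurons.
#'
#' @param traj matrix neurons x bins.
#' @param baseline baseline vector from [baseline_point()].
#' @param n cell count used for the sqrt(n) normalization (default
#'   `nrow(traj)`).
#' @return numeric vector, one distance (a.u.) per bin.
#' @export
distance_from_baseline <- function(traj, baseline, n = nrow(traj)) {
  baseline <- as.numeric(baseline)
  assert_that(length(baseline) == nrow(traj),
              "baseline length must match the neuron count")
  sqrt(colSums((traj - baseline)^2)) / sqrt(n)
}

#' Population trajectory speed
#'
#' Euclidean distance in full dimensional space between neighboring time
#' bins, sqrt(n)-normalized; the series has one fewer entry than the
#' trajectory has bins.
#'
#' @inheritParams distance_from_baseline
#' @return numeric vector of length `ncol(traj) - 1`.
#' @export
trajectory_speed <- function(traj, n = nrow(traj)) {
  d <- traj[, -1, drop = FALSE] - traj[, -ncol(traj), drop = FALSE]
  sqrt(colSums(d^2)) / sqrt(n)
}

#' PCA projection of concatenated condition means
#'
#' Principal components are fit on the concatenation of the condition-mean
#' trajectories (time bins as observations, neurons as variables) and each
#' condition is projected onto the top two components. This is a
#' visualization aid only; distance and speed are always computed in the
#' full-dimensional space.
#'
#' @param cond_means named list of neurons x bins matrices (the same
#'   neurons in the same order).
#' @return list with `projections` (per condition, bins x 2), `sdev`,
#'   `rotation` and `var_explained`.
#' @export
pca_projection <- function(cond_means) {
  X <- t(do.call(cbind, cond_means))  # (sum of bins) x neurons
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  proj <- lapply(cond_means, function(m)
    scale(t(m), center = pc$center, scale = FALSE) %*%
      pc$rotation[, seq_len(k), drop = FALSE])
  list(projections = proj, sdev = pc$sdev,
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Per-bin condition comparison across sessions
#'
#' Tests, separately for each time bin, whether the per-session difference
#' between two conditions is nonzero while adjusting for animal and day as
#' categorical factors (two-way ANOVA reading: the condition effect is the
#' intercept of `difference ~ animal + day` under sum-to-zero contrasts).
#' P-values are Benjamini-Hochberg-adjusted across bins and the rejection
#' mask uses adjusted p < `alpha` (default 0.01).
#'
#' @param diffs matrix sessions x bins of per-session condition differences.
#' @param animal,day factors (or vectors) of length `nrow(diffs)`.
#' @param alpha adjusted-p threshold (default 0.01).
#' @return data.frame with `bin`, `mean_diff`, `p`, `p_adj`, `reject`.
#' @export
per_bin_condition_test <- function(diffs, animal, day, alpha = 0.01) {
  diffs <- as.matrix(diffs)
  assert_that(nrow(diffs) >= 2, "need at least 2 sessions")
  animal <- factor(animal)
  day <- factor(day)
  assert_that(length(animal) == nrow(diffs) && length(day) == nrow(diffs),
              "animal/day must have one entry per session")
  p <- vapply(seq_len(ncol(diffs)), function(b) {
    d <- diffs[, b]
    if (all(abs(d - d[1]) < 1e-12) && abs(d[1]) < 1e-12) return(1)
    terms <- c(if (nlevels(animal) > 1) "animal",
               if (nlevels(day) > 1) "day")
    df <- data.frame(d = d, animal = animal, day = day)
    fm <- stats::as.formula(paste("d ~", paste(c("1", terms),
                                               collapse = " + ")))
    ctr <- stats::setNames(
      rep(list("contr.sum"), length(terms)), terms)
    fit <- stats::lm(fm, data = df,
                     contrasts = if (length(terms)) ctr else NULL)
    co <- summary(fit)$coefficients
    if (!"(Intercept)" %in% rownames(co) ||
        is.na(co["(Intercept)", 4])) return(NA_real_)
    co["(Intercept)", 4]
  }, numeric(1))
  p_adj <- stats::p.adjust(p, "BH")
  data.frame(bin = seq_len(ncol(diffs)),
             mean_diff = colMeans(diffs),
             p = p, p_adj = p_adj,
             reject = !is.na(p_adj) & p_adj < alpha)
}
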