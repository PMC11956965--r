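#' Time-decoding parameters
#'
#' Defaults follow the published setup: elapsed time is decoded within the
#' short delay, between the 1.1 and 3.4 s time points, as 7 classes of
#' 1/3 s each, with the score being the Pearson correlation of actual and
#' predicted class indices (0 is chance, 1 perfect).
#'
#' @param window decoding window in seconds (default `c(1.1, 3.4)`).
#' @param class_bin class width in seconds (default 1/3).
#' @param cv_folds cross-validation folds over trials (default 5).
#' @param cost soft-margin cost of the linear classifier (default 1).
#' @return a list of class `decode_params`.
#' @export
decode_params <- function(window = c(1.1, 3.4), class_bin = 1 / 3,
                          cv_folds = 5, cost = 1) {
  assert_that(length(window) == 2 && window[2] > window[1],
              "window must be increasing", config_error)
  # the published window (1.1-3.4 s) and bin (1/3 s) only divide "within
  # rounding" (6.9 -> 7 classes), so require a well-defined nearest count
  k <- (window[2] - window[1]) / class_bin
  assert_that(round(k) >= 1 && abs(k - round(k)) < 0.5 - 1e-9,
              "window length must divide into class_bin within rounding",
              config_error)
  assert_that(is_count(cv_folds) && cv_folds >= 2,
              "cv_folds must be an integer >= 2", config_error)
  assert_that(cost > 0, "cost must be positive", config_error)
  structure(list(window = window, class_bin = class_bin,
                 cv_folds = as.integer(cv_folds), cost = cost),
            class = c("decode_params", "list"))
}

#' Class labels for time decoding
#'
#' Partitions `[window[1], window[2])` into consecutive `class_bin`-wide
#' intervals.
#'
#' @param params a [decode_params()].
#' @return list with `starts`, `centers` and `n` (the class count;
#'   7 with defaults).
#' @export
class_labels <- function(params = decode_params()) {
  n <- as.integer(round((params$window[2] - params$window[1]) /
                          params$class_bin))
  starts <- params$window[1] + (seq_len(n) - 1) * params$class_bin
  list(starts = starts, centers = starts + params$class_bin / 2, n = n)
}

# Linear max-margin binary classifier: primal squared-hinge objective
#   1/2 ||w||^2 + cost * sum_i max(0, 1 - y_i (w.x_i + b))^2
# minimized with L-BFGS from a zero start (deterministic).
svm2_fit <- function(X, y, cost = 1) {
  d <- ncol(X)
  obj <- function(th) {
    f <- drop(X %*% th[-1]) + th[1]
    m <- pmax(1 - y * f, 0)
    0.5 * sum(th[-1]^2) + cost * sum(m^2)
  }
  grad <- function(th) {
    f <- drop(X %*% th[-1]) + th[1]
    m <- pmax(1 - y * f, 0)
    gy <- m * y
    c(-2 * cost * sum(gy),
      th[-1] - 2 * cost * drop(crossprod(X, gy)))
  }
  stats::optim(numeric(d + 1), obj, grad, method = "L-BFGS-B",
               control = list(maxit = 200))$par
}

svm2_decision <- function(theta, X) drop(X %*% theta[-1]) + theta[1]

#' Decode elapsed time from population activity
#'
#' Each trial contributes one population vector per class bin (the mean of
#' the aligned bins whose centers fall inside that class interval); labels
#' are the class indices. A linear max-margin classifier is trained for
#' every class pair (one-vs-one decomposition) and test samples are
#' assigned by vote count (ties to the smallest class index), under
#' stratified k-fold cross-validation over trials — all bins of a trial
#' stay in one fold, so no within-trial leakage. The score is the Pearson
#' correlation of actual vs predicted class indices over held-out samples
#' (defined as 0 when the predictions are constant).
#'
#' @param aligned an `aligned_activity` (conditioned activity).
#' @param trial_idx trial-table indices of the condition's trials.
#' @param params a [decode_params()].
#' @param seed integer seed for fold assignment (and label permutation).
#' @param permute_labels if `TRUE`, class labels are permuted uniformly at
#'   random across all samples before training — the chance-level control.
#' @return list with `score`, `actual`, `predicted`, `confusion`
#'   (actual x predicted counts) and `classes` (from [class_labels()]).
#' @export
decode_time <- function(aligned, trial_idx, params = decode_params(),
                        seed = 1L, permute_labels = FALSE) {
  set.seed(seed)
  cl <- class_labels(params)
  n_trials <- length(trial_idx)
  if (n_trials < params$cv_folds)
    validation_error(sprintf(
      "each class has %d trials, fewer than %d folds", n_trials,
      params$cv_folds))
  sub <- subset_trials(aligned, trial_idx)
  ta <- sub$time_axis
  n_neurons <- dim(sub$tensor)[1]
  feat <- vector("list", cl$n)
  for (k in seq_len(cl$n)) {
    cols <- which(ta >= cl$starts[k] &
                    ta < cl$starts[k] + params$class_bin)
    assert_that(length(cols) >= 1,
                sprintf("no aligned bins inside class %d", k))
    feat[[k]] <- t(apply(sub$tensor[, , cols, drop = FALSE], c(1, 2),
                         mean))  # trials x neurons
  }
  X <- do.call(rbind, feat)
  y <- rep(seq_len(cl$n), each = n_trials)
  trial_of <- rep(seq_len(n_trials), times = cl$n)
  if (permute_labels) y <- sample(y)
  folds <- sample(rep_len(seq_len(params$cv_folds), n_trials))
  predicted <- integer(length(y))
  pairs <- utils::combn(cl$n, 2)
  for (f in seq_len(params$cv_folds)) {
    test <- folds[trial_of] == f
    votes <- matrix(0L, sum(test), cl$n)
    for (pcol in seq_len(ncol(pairs))) {
      i <- pairs[1, pcol]; j <- pairs[2, pcol]
      tr_sel <- !test & (y == i | y == j)
      if (!any(y[tr_sel] == i) || !any(y[tr_sel] == j)) next
      th <- svm2_fit(X[tr_sel, , drop = FALSE],
                     ifelse(y[tr_sel] == i, 1, -1), cost = params$cost)
      dec <- svm2_decision(th, X[test, , drop = FALSE])
      win <- ifelse(dec >= 0, i, j)
      votes[cbind(seq_len(sum(test)), win)] <-
        votes[cbind(seq_len(sum(test)), win)] + 1L
    }
    predicted[test] <- max.col(votes, ties.method = "first")
  }
  score <- if (stats::sd(predicted) == 0 || stats::sd(y) == 0) 0 else
    stats::cor(y, predicted)
  confusion <- table(factor(y, levels = seq_len(cl$n)),
                     factor(predicted, levels = seq_len(cl$n)))
  list(score = score, actual = y, predicted = predicted,
       confusion = confusion, classes = cl)
}
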