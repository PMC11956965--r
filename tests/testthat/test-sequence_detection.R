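test_that("preferred trial type follows the larger average peak, ties to short", {
  ses <- cached_session()
  al <- ses$aligned; tr <- ses$rec$trials; cfg <- ses$cfg
  truth <- ses$truth
  seq_cells <- truth[truth$role == "sequence", ]
  for (nr in seq_cells$neuron[1:8]) {
    pref <- preferred_trial_type(al, tr, cfg, nr)
    want <- if (seq_cells$preferred_odor[seq_cells$neuron == nr] == "A")
      "short" else "long"
    expect_equal(pref$preferred, want)
  }
  # constructed tie (all-zero neuron) resolves to short
  zero <- make_aligned(array(0, c(1, nrow(tr), 80)),
                       trial_index = tr$index)
  expect_equal(preferred_trial_type(zero, tr, cfg, 1)$preferred, "short")
})

test_that("circular shuffle test fails shift-invariant activity and is seeded", {
  params <- detection_params(n_shuffles = 500)
  zero <- matrix(0, 10, 20)
  r0 <- circular_shuffle_test(zero, params, seed = 1)
  expect_false(r0$pass)
  expect_equal(r0$observed, 0)

  # constant-in-time trials: every shuffle maximum equals the observed peak
  const <- matrix(rep(runif(10), 20), 10, 20)
  rc <- circular_shuffle_test(const, params, seed = 2)
  expect_equal(rc$threshold, rc$observed, tolerance = 1e-12)
  expect_false(rc$pass)

  # deterministic under a seed
  set.seed(3); sl <- matrix(abs(rnorm(8 * 22)), 8, 22)
  expect_equal(circular_shuffle_test(sl, params, seed = 4),
               circular_shuffle_test(sl, params, seed = 4))
  expect_error(circular_shuffle_test(sl[1, , drop = FALSE], params),
               class = "seqtime_validation_error")
})

test_that("rotating all trials by a common offset rotates the peak", {
  set.seed(6)
  slice <- matrix(abs(rnorm(12 * 20)), 12, 20)
  peak_of <- function(s) which.max(colMeans(s))
  base <- peak_of(slice)
  for (k in c(3, 11)) {
    rot <- slice[, c((seq_len(20) - 1 - k) %% 20 + 1)]
    expect_equal(peak_of(rot), (base - 1 + k) %% 20 + 1)
  }
})

test_that("reliability counts events in a closed +/-0.5 s window", {
  ta <- seq(0.05, 3.45, by = 0.1)  # bin centers
  peak <- 1.95
  slice <- matrix(0, 4, length(ta))
  slice[1, which(abs(ta - peak) < 1e-9)] <- 3       # at the peak
  slice[2, which(abs(ta - (peak + 0.5)) < 1e-9)] <- 3  # exactly at +0.5 s
  slice[3, which(abs(ta - (peak + 0.6)) < 1e-9)] <- 3  # outside
  expect_equal(reliability_fraction(slice, ta, peak, detection_params()),
               2 / 4)
  # sub-threshold events never count
  slice[4, which(abs(ta - peak) < 1e-9)] <- 1.5
  expect_equal(reliability_fraction(slice, ta, peak, detection_params()),
               2 / 4)
})

test_that("detection recovers planted cells and rejects silence", {
  ses <- cached_session()
  al <- ses$aligned; tr <- ses$rec$trials; cfg <- ses$cfg
  st <- detect_sequence_cells(al, tr, cfg,
                              detection_params(n_shuffles = 1000),
                              seed = 42)
  truth <- ses$truth
  m <- merge(truth[truth$role == "sequence", ], st, by = "neuron")
  expect_gte(mean(m$significant), 0.9)
  expect_true(all(m$preferred_odor.x[m$significant] ==
                    m$preferred_odor.y[m$significant]))
  planted_bin <- vapply(m$center_s, function(cs)
    which.min(abs(al$time_axis - cs)), integer(1))
  expect_true(all(abs(m$peak_bin[m$significant] -
                        planted_bin[m$significant]) <= 1))
  # significance invariant holds row by row
  expect_true(all(!st$significant |
                    (st$observed_peak > st$shuffle_threshold &
                       st$reliability >= 0.2)))

  # an all-zero session yields zero significant cells
  zero <- make_aligned(array(0, c(3, nrow(tr), 80)), trial_index = tr$index)
  st0 <- detect_sequence_cells(zero, tr, cfg,
                               detection_params(n_shuffles = 200), seed = 1)
  expect_equal(sum(st0$significant), 0)
})

test_that("sequence heatmaps sort by peak and normalize rows", {
  ses <- cached_session()
  al <- ses$aligned; tr <- ses$rec$trials
  # three synthetic cells with centers at 1, 2, 3 s, planted directly
  ta <- al$time_axis
  tens <- array(0, c(3, nrow(tr), length(ta)))
  amps <- c(5, 1, 3)  # amplitudes must not affect the order
  for (i in 1:3) {
    b <- which.min(abs(ta - i))
    tens[i, , b] <- amps[i]
  }
  alx <- make_aligned(tens, trial_index = tr$index)
  stats <- data.frame(neuron = c(2, 3, 1),
                      preferred = "short", preferred_odor = "A",
                      peak_bin = vapply(c(2, 3, 1), function(i)
                        which.min(abs(ta - i)), integer(1)),
                      peak_time = c(2, 3, 1), significant = TRUE)
  hm <- sequence_heatmap(alx, tr, stats, "short")
  expect_equal(attr(hm, "neurons"), c(1, 2, 3))
  expect_equal(unname(apply(hm, 1, max)), rep(1, 3))  # normalized rows
  expect_true(all(diff(apply(hm, 1, which.max)) > 0))  # diagonal band
})

test_that("peak-distribution comparisons behave at the extremes", {
  x <- c(0.5, 1.2, 2.8, 3.1)
  same <- compare_peak_distributions(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  disj <- compare_peak_distributions(c(0.1, 0.4, 0.8), c(2.1, 2.6, 3.2))
  expect_equal(disj$statistic, 1)
  # peaks outside the window are ignored
  win <- compare_peak_distributions(c(x, 9), c(x, 10), window = c(0, 3.5))
  expect_equal(win$n_short, 4)
})

test_that("binned peak fractions sum to one and identical sets never reject", {
  mk <- function(short_pk, long_pk) {
    data.frame(neuron = seq_along(c(short_pk, long_pk)),
               preferred = rep(c("short", "long"),
                               c(length(short_pk), length(long_pk))),
               peak_time = c(short_pk, long_pk), significant = TRUE)
  }
  pk <- c(0.2, 0.7, 1.4, 2.2, 3.3)
  res <- binned_peak_fractions(list(mk(pk, pk), mk(pk, pk), mk(pk, pk)))
  expect_true(all(res$tests$p_adj == 1))
  sums <- apply(res$fractions, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_error(binned_peak_fractions(list(mk(pk, pk))),
               class = "seqtime_validation_error")
})
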