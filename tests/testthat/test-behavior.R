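test_that("trial scoring uses the half-open 3-s response window", {
  o2 <- 100
  expect_true(score_trial(o2 + 0.5, o2, is_match = FALSE))   # lick in window
  expect_false(score_trial(o2 + 2.9, o2, is_match = TRUE))   # match + lick
  expect_false(score_trial(o2 + 3.0, o2, is_match = FALSE))  # boundary: out
  expect_true(score_trial(o2 + 2.999, o2, is_match = FALSE))
  expect_true(score_trial(numeric(0), o2, is_match = TRUE))
  # licks outside the window are ignored, not scored
  expect_true(score_trial(c(o2 - 5, o2 + 10), o2, is_match = TRUE))
})

test_that("behavior summaries are exact and handle empty categories", {
  cfg <- small_cfg()
  tr <- generate_trials(task_config(iti = 2, reverse_fraction = 0), seed = 1)
  # plant outcomes by hand: first 10 non-match trials get a lick at +0.4 s
  nm <- which(!tr$is_match)[1:10]
  for (i in nm) tr$licks[[i]] <- tr$odor2_onset[i] + 0.4
  tr <- score_trials(tr, cfg)
  s <- summarize_behavior(tr, cfg)
  # accuracy is exactly 100 * k/m per category
  std_short <- s[s$category == "standard_short", ]
  idx <- trial_categories(tr, cfg) == "standard_short"
  expect_equal(std_short$accuracy_pct,
               100 * sum(tr$correct[idx]) / sum(idx))
  # no reverse trials: reverse categories reported absent, not zero
  expect_true(is.na(s$accuracy_pct[s$category == "reverse_short"]))
  expect_equal(s$n_trials[s$category == "reverse_short"], 0L)

  # median latency ignores licks after the first within the window
  tr2 <- tr
  for (i in nm) tr2$licks[[i]] <- c(tr2$licks[[i]],
                                    tr2$odor2_onset[i] + c(1, 2, 2.5))
  s2 <- summarize_behavior(score_trials(tr2, cfg), cfg)
  expect_equal(s2$median_latency_ms, s$median_latency_ms)
})

test_that("paired category tests behave at the extremes and under the null", {
  a <- c(80, 85, 90, 95)
  expect_equal(paired_category_test(a, a)$p.value, 1)
  set.seed(2)
  shifted <- paired_category_test(a + 20 + rnorm(4, sd = 0.01), a)
  expect_lt(shifted$p.value, 1e-4)
  expect_error(paired_category_test(1, 1),
               class = "seqtime_validation_error")
  # type-I error at the nominal level over 1000 null replicates
  hits <- 0
  for (i in 1:1000) {
    x <- rnorm(8); y <- rnorm(8)
    if (paired_category_test(x, y)$p.value < 0.05) hits <- hits + 1
  }
  expect_lt(abs(hits / 1000 - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("locomotion z-binning matches direct arithmetic", {
  # constant trace -> all zeros (zero-variance rule)
  zc <- locomotion_zbin(rep(2, 100), 30.9)
  expect_true(all(zc$values == 0))
  # hand toy: 20 bins of 5 frames
  set.seed(3)
  trace <- abs(rnorm(100))
  zb <- locomotion_zbin(trace, 30.9)
  binned <- colMeans(matrix(trace, 5))
  z <- (binned - mean(binned)) / sd(binned)
  z[z < 1] <- 0
  expect_equal(zb$values, z)
  expect_equal(zb$bin_seconds, 5 / 30.9)
  # a single large bout: only its bins survive the floor
  trace2 <- rep(0.1, 200); trace2[51:100] <- 5
  zb2 <- locomotion_zbin(trace2, 30.9)
  expect_true(all(which(zb2$values > 0) %in% 11:20))
})

test_that("bout detection honors the closed 1-s threshold", {
  bs <- 5 / 30.9  # 0.1618 s per bin
  mk <- function(n_hot) {
    v <- rep(0, 40); if (n_hot > 0) v[10 + seq_len(n_hot)] <- 2
    list(values = v, bin_seconds = bs,
         bin_times = ((seq_len(40) - 1) * 5 + 2.5) / 30.9)
  }
  # 5 bins = 0.81 s -> no bout; 7 bins = 1.13 s -> bout
  expect_equal(nrow(running_bouts(mk(5))), 0)
  b7 <- running_bouts(mk(7))
  expect_equal(nrow(b7), 1)
  expect_equal(b7$duration_s, 7 * bs)
  # exactly 1.0 s: closed threshold counts it (bin width chosen to divide 1 s)
  zb1 <- list(values = c(rep(0, 5), rep(2, 10), rep(0, 5)),
              bin_seconds = 0.1, bin_times = seq(0.05, 1.95, by = 0.1))
  expect_equal(nrow(running_bouts(zb1)), 1)
  # idempotence and zero-padding invariance
  padded <- mk(7); padded$values <- c(padded$values, rep(0, 20))
  expect_equal(running_bouts(padded)[, c("start_bin", "end_bin")],
               b7[, c("start_bin", "end_bin")])
})

test_that("running flags drive trial exclusion", {
  ses <- cached_session()
  tr <- ses$rec$trials; cfg <- ses$cfg
  zb <- locomotion_zbin(ses$rec$locomotion, cfg$frame_rate)
  flags <- trial_running_flags(running_bouts(zb), tr, cfg)
  expect_setequal(which(flags), ses$bout_trials)
  al <- ses$aligned
  kept <- exclude_running(al, flags)
  expect_equal(dim(kept$tensor)[2], sum(!flags))
  expect_true(all(!flags[kept$trial_index]))
  # no running trials -> identity
  none <- exclude_running(al, rep(FALSE, nrow(tr)))
  expect_equal(none$trial_index, al$trial_index)
  # all running -> empty tensor, downstream raises insufficient-trials
  all_run <- exclude_running(al, rep(TRUE, nrow(tr)))
  expect_equal(dim(all_run$tensor)[2], 0)
  expect_error(odor_information(discretize_activity(all_run),
                                all_run$trial_index),
               class = "seqtime_validation_error")
})
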