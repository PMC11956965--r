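test_that("trial schedules have the stated block structure", {
  cfg <- task_config()  # 7 blocks x 20 trials, reverse 0.2
  for (seed in c(1, 99)) {
    tr <- generate_trials(cfg, seed = seed)
    expect_equal(nrow(tr), 140)
    pairs <- table(tr$odor1, tr$odor2)
    expect_true(all(pairs == 35))
    expect_equal(sum(tr$is_reverse), 28)  # round(0.2 * 140), by count
    # four pairs appear equally often within every block
    per_block <- tapply(seq_len(nrow(tr)), tr$block, function(i)
      table(paste0(tr$odor1[i], tr$odor2[i])))
    for (tb in per_block) expect_true(all(tb == 5))
    # delays follow the map, swapped on reverse trials
    std <- unname(cfg$delay_map[tr$odor1])
    expect_equal(tr$delay[!tr$is_reverse], std[!tr$is_reverse])
    expect_equal(tr$delay[tr$is_reverse], 7.5 - std[tr$is_reverse])
    expect_equal(tr$odor2_onset, tr$odor1_onset + 1 + tr$delay)
    expect_equal(tr$is_match, tr$odor1 == tr$odor2)
  }
  # reverse_fraction 0: every delay equals the cue's standard delay
  tr0 <- generate_trials(task_config(reverse_fraction = 0), seed = 5)
  expect_false(any(tr0$is_reverse))
  expect_equal(tr0$delay, unname(task_config()$delay_map[tr0$odor1]))
  # determinism
  expect_identical(generate_trials(cfg, seed = 8),
                   generate_trials(cfg, seed = 8))
  expect_error(generate_trials(task_config(trials_per_block = 18)),
               "divisible", class = "seqtime_config_error")
})

test_that("planted cells produce transients where and when planted", {
  cfg <- small_cfg()
  tr <- generate_trials(cfg, seed = 1)
  # one perfectly reliable noise-free cell centered at 2.0 s
  p <- small_params(n_sequence_cells = c(1, 0), n_second_odor_cells = 0,
                    n_noise_cells = 0, reliability = 1, noise_sd = 0,
                    background_rate = 0, overrep_weight = 0)
  set.seed(2)
  truth <- NULL
  repeat {  # redraw until the planted center is near 2.0 s for a sharp check
    g <- generate_neurons(cfg, tr, p)
    if (abs(g$truth$center_s[1] - 2) < 1.2) { truth <- g; break }
  }
  center <- truth$truth$center_s[1]
  fr <- cfg$frame_rate
  on_pref <- tr$odor1 == "A"  # "A" cues the short delay by default
  peak_frames <- round((tr$odor1_onset[on_pref] + center) * fr)
  expect_true(all(truth$activity[1, peak_frames] > 0.9 * p$amplitude))
  # flat away from the field on non-preferred trials
  off_frames <- round((tr$odor1_onset[!on_pref] + center) * fr)
  expect_true(all(truth$activity[1, off_frames] == 0))

  # reliability 0 -> indistinguishable from silence (no background here)
  p0 <- small_params(n_sequence_cells = c(1, 0), n_second_odor_cells = 0,
                     n_noise_cells = 0, reliability = 0, noise_sd = 0,
                     background_rate = 0)
  g0 <- generate_neurons(cfg, tr, p0, seed = 3)
  expect_true(all(g0$activity == 0))
})

test_that("over-representation weight shifts planted centers into the last 0.5 s", {
  cfg <- small_cfg()
  frac_late <- function(w, seed) {
    p <- generator_params(n_sequence_cells = c(400, 0),
                          n_second_odor_cells = 0, n_noise_cells = 0,
                          overrep_weight = w)
    set.seed(seed)
    truth <- seqtime:::draw_planted_cells(cfg, p)
    mean(truth$center_s >= 3.0 & truth$center_s <= 3.5)
  }
  f <- vapply(c(0, 0.2, 0.5), frac_late, numeric(1), seed = 10)
  expect_true(all(diff(f) > 0))
  # weight 0 leaves the uniform share, ~0.5/3.5
  expect_lt(abs(f[1] - 0.5 / 3.5), 0.08)
})

test_that("behavior generator plants accuracies and latency shifts", {
  cfg <- small_cfg()
  tr <- generate_trials(cfg, seed = 4)
  # accuracy 1 everywhere -> scorer returns 100% in every category
  p1 <- small_params(behavior = list(
    accuracy = c(standard_short = 1, standard_long = 1,
                 reverse_short = 1, reverse_long = 1)))
  b1 <- suppressWarnings(generate_behavior(tr, cfg, p1, seed = 5))
  s1 <- summarize_behavior(score_trials(b1, cfg), cfg)
  expect_true(all(s1$accuracy_pct == 100))
  # generated outcomes agree with the scorer trial by trial
  expect_equal(score_trials(b1, cfg)$correct, b1$correct)

  # degenerate SD 0: the planted +21 ms reverse shift is exact
  p2 <- small_params(behavior = list(latency_sd = 0))
  b2 <- suppressWarnings(generate_behavior(tr, cfg, p2, seed = 6))
  s2 <- summarize_behavior(score_trials(b2, cfg), cfg)
  lat <- function(cat) s2$median_latency_ms[s2$category == cat]
  expect_equal(lat("reverse") - lat("standard"), 21, tolerance = 1e-9)

  # planted accuracies recovered within a binomial CI on a long session
  big <- task_config(iti = 2, n_blocks = 70)  # 1400 trials
  trb <- generate_trials(big, seed = 7)
  pb <- small_params(behavior = list(
    accuracy = c(standard_short = 0.875, standard_long = 0.86,
                 reverse_short = 0.868, reverse_long = 0.81)))
  bb <- suppressWarnings(generate_behavior(trb, big, pb, seed = 8))
  sb <- summarize_behavior(score_trials(bb, big), big)
  for (cat in names(pb$behavior$accuracy)) {
    row <- sb[sb$category == cat, ]
    p0 <- pb$behavior$accuracy[[cat]]
    margin <- 4 * sqrt(p0 * (1 - p0) / row$n_trials)
    expect_lt(abs(row$accuracy_pct / 100 - p0), margin)
  }

  # latency mass outside the response window -> warning + truncation
  p3 <- small_params(behavior = list(latency_mean = 5, latency_sd = 0.1))
  expect_warning(b3 <- generate_behavior(tr, cfg, p3, seed = 9),
                 "response window")
  lat <- b3$first_lick_latency[!is.na(b3$first_lick_latency)]
  expect_true(all(lat >= 0 & lat < cfg$response_window))
})

test_that("locomotion generator plants bouts at the configured rate", {
  cfg <- small_cfg()
  tr <- generate_trials(cfg, seed = 9)
  run_fraction <- function(bout_prob, seed) {
    p <- small_params(locomotion = list(bout_prob = bout_prob))
    g <- generate_locomotion(tr, cfg, p, seed = seed)
    zb <- locomotion_zbin(g$trace, cfg$frame_rate)
    flags <- trial_running_flags(running_bouts(zb), tr, cfg)
    list(frac = mean(flags), flags = flags, planted = g$bout_trials)
  }
  expect_equal(run_fraction(0, 20)$frac, 0)
  r <- run_fraction(0.3, 21)
  expect_lt(abs(r$frac - 0.3), 4 * sqrt(0.3 * 0.7 / nrow(tr)))
  # planted bouts are exactly the flagged trials
  expect_setequal(which(r$flags), r$planted)
})

test_that("generate_session is deterministic in (params, seed)", {
  cfg <- small_cfg(n_blocks = 1)
  p <- small_params(n_sequence_cells = 3, n_noise_cells = 5)
  a <- suppressWarnings(generate_session(cfg, p, seed = 123))
  b <- suppressWarnings(generate_session(cfg, p, seed = 123))
  expect_identical(a$recording$activity, b$recording$activity)
  expect_identical(a$recording$trials, b$recording$trials)
  expect_identical(a$recording$locomotion, b$recording$locomotion)
  expect_identical(a$truth, b$truth)
})
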