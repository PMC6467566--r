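neutral_unit <- function(...) {
  unit_params(nogo_gain = 1, cue_offset = c(TASK1 = 0, TASK2 = 0),
              adaptation_strength = 0, motor_ramp_amp = 0,
              trial_gain_sd = 0, forward_suppression = 0, ...)
}

test_that("with all modulation off the rate profile is task-invariant", {
  u <- neutral_unit()
  grid <- seq(0, 3.59, by = 0.001)
  p1 <- build_rate_profile(u, toy_trial(task = "TASK1"))
  p2 <- build_rate_profile(u, toy_trial(task = "TASK2"))
  expect_equal(p1$fn(grid), p2$fn(grid), tolerance = 1e-12)
})

test_that("no-go gain raises the during-window mean by the closed-form factor", {
  # the no-go differential switches on 70 ms after tone onset, so the
  # window-mean ratio is (0.07 + 0.18 g) / 0.25 for the 250 ms window
  for (g in c(1.15, 1.3, 1.6)) {
    u <- unit_params(nogo_gain = g, cue_offset = c(TASK1 = 0, TASK2 = 0),
                     adaptation_strength = 0, motor_ramp_amp = 0,
                     trial_gain_sd = 0)
    # S1 = 3 kHz is S1-no-go in Task 2 and S1-uncertain in Task 1
    p2 <- build_rate_profile(u, toy_trial(task = "TASK2"))
    p1 <- build_rate_profile(u, toy_trial(task = "TASK1"))
    grid <- seq(1.0, 1.25, length.out = 50001)
    grid <- grid[-length(grid)] + diff(grid)[1] / 2
    ratio <- mean(p2$fn(grid)) / mean(p1$fn(grid))
    expect_equal(ratio, (0.07 + 0.18 * g) / 0.25, tolerance = 1e-4)
  }
  # monotonicity of the induced ratio in the gain
  gains <- c(1.0, 1.15, 1.3)
  ratios <- vapply(gains, function(g) (0.07 + 0.18 * g) / 0.25, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("forward suppression scales the S2 evoked elevation directly", {
  u <- neutral_unit()
  u$forward_suppression <- 0.5
  tr <- toy_trial(task = "TASK1", s1_freq = 3000, s2_freq = 3000,
                  outcome = "CORRECT_REJECTION")
  p <- build_rate_profile(u, tr)
  base <- p$fn(0.5)
  s1_amp <- p$fn(1.1) - base
  s2_amp <- p$fn(2.1) - base
  expect_equal(s2_amp, 0.5 * s1_amp, tolerance = 1e-12)
  # different frequencies: no suppression
  tr2 <- toy_trial(task = "TASK2", s1_freq = 1000, s2_freq = 3000)
  u2 <- neutral_unit(best_frequency = 3000, tuning_bandwidth = 1e6)
  u2$forward_suppression <- 0.5
  p2 <- build_rate_profile(u2, tr2)
  expect_equal(p2$fn(2.1) - p2$fn(0.5), p2$fn(1.1) - p2$fn(0.5),
               tolerance = 1e-9)
})

test_that("motor ramp peaks 200 ms before the release and only on release trials", {
  u <- neutral_unit()
  u$motor_ramp_amp <- 30
  rel <- 2.9
  tr <- toy_trial(task = "TASK1", s1_freq = 3000, s2_freq = 3000,
                  outcome = "HIT", t_release = rel)
  p <- build_rate_profile(u, tr)
  base <- p$fn(0.5)
  expect_equal(p$fn(rel - 0.2) - base, 30, tolerance = 1e-9)
  expect_equal(p$fn(rel - 0.31), base, tolerance = 1e-9)
  no_rel <- build_rate_profile(u, toy_trial(task = "TASK1", s1_freq = 3000,
                                            s2_freq = 3000))
  expect_equal(no_rel$fn(rel - 0.2), base, tolerance = 1e-9)
})

test_that("thinning respects the profile support and Poisson statistics", {
  # zero profile -> no spikes
  zero <- list(fn = function(t) rep(0, length(t)), t_end = 1, sup = 0)
  expect_length(simulate_spike_train(zero), 0)
  # step profile: nothing before the step
  step <- list(fn = function(t) ifelse(t >= 0.5, 50, 0), t_end = 1, sup = 50)
  set.seed(3)
  for (i in 1:20) expect_true(all(simulate_spike_train(step) >= 0.5))
  # constant profile: mean count within Monte-Carlo tolerance of Poisson
  const <- list(fn = function(t) rep(20, length(t)), t_end = 1, sup = 20)
  set.seed(4)
  counts <- vapply(seq_len(4000), function(i) length(simulate_spike_train(const)), 0)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 4000))
  expect_error(simulate_spike_train(list(fn = identity, t_end = 1, sup = Inf)),
               "finite")
})

test_that("sequence schedules have the study's probability structure", {
  s1 <- sequence_schedule("TASK1", 0.60)
  expect_equal(sum(s1), 1)
  p <- tone_probabilities(s1)
  expect_equal(unname(p["3000"]), 0.60 + 0.40 / 3, tolerance = 1e-12)
  p2 <- tone_probabilities(sequence_schedule("TASK2", 0.60))
  expect_equal(unname(p2["3000"]), 2 * 0.40 / 3, tolerance = 1e-12)
  expect_error(sequence_schedule("TASK1", 0.45), "go_fraction")
  expect_error(sequence_schedule("TASK1", 0.80), "go_fraction")
  expect_error(tone_probabilities(c(`3-3` = 0.5, `3-1` = 0.1, `1-3` = 0.1,
                                    `1-1` = 0.1)), "sum to 1")
})

test_that("generated sessions honour the stratified go fraction and block design", {
  s <- small_session()
  ev <- s$events
  task_ev <- ev[ev$phase == "task", ]
  for (b in unique(task_ev$block_id)) {
    blk <- task_ev[task_ev$block_id == b, ]
    expect_equal(sum(blk$required == "GO"), round(0.6 * nrow(blk)))
    expect_length(unique(blk$task), 1)
  }
  # passive blocks carry inter-sequence intervals in [3.5, 4.5]
  pas <- ev[ev$phase == "passive", ]
  expect_true(all(pas$iti >= 3.5 & pas$iti <= 4.5))
  expect_true(all(is.na(pas$outcome)))
  # referential integrity of the spike and LFP containers
  expect_true(all(s$spikes$trial_id %in% ev$trial_id))
  expect_true(all(s$lfp[[1]]$trial_ids %in% ev$trial_id))
  # spike times inside the trial span
  expect_true(all(s$spikes$time >= 0 & s$spikes$time <= max(ev$t_end)))
})

test_that("zero false-alarm rate yields no false alarms", {
  cfg <- session_config(n_units = 1, n_lfp_sites = 0, trials_per_block = 60,
                        n_blocks_per_task = 1, include_passive = FALSE,
                        include_bf_block = FALSE, fa_rate_s1nogo = 0,
                        fa_rate_s2nogo = 0, seed = 2)
  s <- generate_session(cfg)
  expect_false(any(s$events$outcome == "FALSE_ALARM", na.rm = TRUE))
})

test_that("the tuning block presents 40 log-spaced tones ten times each", {
  cfg <- session_config(n_units = 1, n_lfp_sites = 0, trials_per_block = 20,
                        n_blocks_per_task = 1, include_passive = FALSE,
                        include_bf_block = TRUE, seed = 3)
  s <- generate_session(cfg)
  bf <- s$events[s$events$phase == "bf", ]
  expect_equal(nrow(bf), 400)
  freqs <- sort(unique(bf$s1_freq))
  expect_length(freqs, 40)
  expect_equal(min(freqs), 62.5, tolerance = 1e-9)
  expect_equal(max(freqs), 16000, tolerance = 1e-9)
  # equidistant on a log2 axis over 8 octaves
  expect_equal(diff(log2(freqs)), rep(8 / 39, 39), tolerance = 1e-9)
  expect_true(all(table(bf$s1_freq) == 10))
  expect_true(all(bf$tone_duration == 0.1))
})

test_that("a fixed seed regenerates an identical session", {
  cfg <- session_config(n_units = 2, n_lfp_sites = 1, trials_per_block = 30,
                        n_blocks_per_task = 1, include_bf_block = FALSE,
                        seed = 99)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$events, b$events)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$lfp[[1]]$data, b$lfp[[1]]$data)
})

test_that("simulated LFP reduces to its closed-form template without noise", {
  quiet <- lfp_params(amplitude = c(0, 0), noise_sd = 0)
  tr <- toy_trial(task = "TASK1")
  expect_true(all(simulate_lfp(quiet, tr)$samples == 0))
  single <- lfp_params(amplitude = c(-0.2, 0), noise_sd = 0)
  x <- simulate_lfp(single, tr)$samples
  expect_equal(max(abs(x)), 0.2, tolerance = 1e-6)
  expect_equal(min(x), -0.2, tolerance = 1e-6)
  # no-go gain on the second deflection raises the during-window RMS
  par <- lfp_params(noise_sd = 0, nogo_gain = 1.5)
  tr_ng <- toy_trial(task = "TASK2", s1_freq = 3000)  # S1-no-go
  tr_un <- toy_trial(task = "TASK1", s1_freq = 3000)  # S1-uncertain
  rms_of <- function(trial) {
    sim <- simulate_lfp(par, trial)
    lfp_rms(sim$samples, sim$sampling_rate, sim$t0, c(1.0, 1.5))
  }
  expect_gt(rms_of(tr_ng), rms_of(tr_un))
})

test_that("configuration validation rejects invalid rates and ranges", {
  expect_error(session_config(go_fraction = 0.4), "go_fraction")
  expect_error(session_config(miss_rate = 1.2), "rates")
  expect_error(session_config(n_units = 0), "n_units")
  expect_error(unit_params(baseline_rate = -1), "baseline_rate")
  expect_error(unit_params(adaptation_strength = 1.5), "\\[0, 1\\]")
  expect_error(lfp_params(sampling_rate = 100), "sampling_rate")
  expect_error(lfp_params(latency = c(0.1, 0.9)), "latencies")
})
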