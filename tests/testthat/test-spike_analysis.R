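test_that("window rates use half-open windows and count correctly", {
  expect_equal(mean_rate(c(0.01, 0.1, 0.2, 0.21, 0.249), c(0, 0.25)), 20)
  expect_equal(mean_rate(numeric(0), c(0, 0.25)), 0)
  # spike exactly at the right edge is excluded, at the left edge included
  expect_equal(mean_rate(c(0.25), c(0, 0.25)), 0)
  expect_equal(mean_rate(c(0), c(0, 0.25)), 4)
  expect_error(mean_rate(1, c(0.5, 0.5)), "positive length")
})

test_that("condition ratio matches hand arithmetic and flooring rules", {
  expect_equal(condition_ratio(c(10, 20, 30), c(10, 10, 10),
                               min_trials = 3), 2)
  expect_equal(condition_ratio(rep(7, 5), rep(7, 5)), 1)
  # per-trial counts (6,4,5,5) and (3,2,3,4) over 0.25 s windows
  num <- c(6, 4, 5, 5) / 0.25
  den <- c(3, 2, 3, 4) / 0.25
  expect_equal(condition_ratio(num, den, min_trials = 4), 20 / 12,
               tolerance = 1e-12)
  expect_error(condition_ratio(c(1, 2), c(1, 2, 3, 4, 5)), "at least 5")
  expect_error(condition_ratio(rep(0, 5), rep(0, 5)), "silent")
  # scale invariance
  set.seed(21)
  a <- rpois(8, 12) * 4
  b <- rpois(8, 12) * 4
  r1 <- condition_ratio(a, b)
  expect_equal(condition_ratio(3.7 * a, 3.7 * b), r1, tolerance = 1e-12)
})

test_that("permutation test agrees with exhaustive enumeration oracles", {
  r <- permutation_test_ratio(c(30, 32, 31), c(10, 11, 12))
  expect_true(r$exact)
  expect_equal(r$p_value, 2 / 20)
  expect_equal(r$p_value, oracle_ratio_perm_p(c(30, 32, 31), c(10, 11, 12)))
  # identical lists tie on every permutation
  expect_equal(permutation_test_ratio(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  # random small instances against the independent oracle
  set.seed(31)
  for (i in 1:10) {
    a <- rpois(3, 20) / 0.25
    b <- rpois(3, 14) / 0.25
    got <- permutation_test_ratio(a, b)
    expect_true(got$exact)
    expect_equal(got$p_value, oracle_ratio_perm_p(a, b), tolerance = 1e-12)
  }
})

test_that("permutation test and its p-values are scale invariant", {
  set.seed(7)
  a <- rpois(6, 25) / 0.25
  b <- rpois(6, 18) / 0.25
  r1 <- permutation_test_ratio(a, b)         # exhaustive: deterministic
  r2 <- permutation_test_ratio(10 * a, 10 * b)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(17)
  ps <- vapply(seq_len(200), function(i) {
    a <- rpois(25, 5) / 0.25
    b <- rpois(25, 5) / 0.25
    permutation_test_ratio(a, b, n_perm = 199)$p_value
  }, 0)
  # super-uniformity within a loose Monte-Carlo band
  expect_lt(mean(ps < 0.05), 0.11)
  expect_lt(mean(ps < 0.2), 0.30)
  expect_gt(mean(ps < 0.5), 0.35)
})

test_that("paired sign-flip test matches its enumeration oracle", {
  set.seed(13)
  x <- rnorm(8, 1)
  y <- rnorm(8)
  got <- paired_permutation_test(x, y, n_perm = 1000)
  expect_true(got$exact)
  expect_equal(got$p_value, oracle_signflip_p(x, y), tolerance = 1e-12)
  expect_equal(paired_permutation_test(1:5, 1:5)$p_value, 1)
})

test_that("PSTH bins count per trial and respect the range", {
  # one spike per trial at a fixed time
  h <- psth(rep(0.123, 100), n_trials = 100, range = c(-0.05, 0.5))
  expect_equal(sum(h$rate > 0), 1)
  expect_equal(max(h$rate), 100)
  expect_equal(h$bin_centers[which.max(h$rate)], 0.125)
  expect_true(all(psth(numeric(0), 10)$rate == 0))
  # homogeneous Poisson rate recovered in every bin
  set.seed(8)
  n_tr <- 2000
  times <- runif(rpois(1, 20 * n_tr), 0, 1)
  h2 <- psth(times, n_tr, range = c(0, 1))
  expect_lt(max(abs(h2$rate - 20)), 20 * 0.35)
  expect_lt(abs(mean(h2$rate) - 20), 0.5)
})

test_that("geometric-mean normalized traces equal the log-domain oracle", {
  expect_equal(
    geometric_average_normalized(matrix(c(2, 8), 2, 1), c(1, 1))$values, 4)
  # all units identical -> that trace
  tr <- matrix(rep(c(1, 2, 4), each = 3), 3, 3)
  expect_equal(geometric_average_normalized(tr, rep(1, 3))$values,
               c(1, 2, 4))
  set.seed(12)
  psths <- matrix(rexp(60, 1 / 15), 6, 10)
  base <- runif(6, 0.05, 20)
  got <- geometric_average_normalized(psths, base)
  expect_equal(got$values, oracle_geo_trace(psths, base), tolerance = 1e-12)
  # invariance to unit order
  perm <- sample(6)
  expect_equal(geometric_average_normalized(psths[perm, ], base[perm])$values,
               got$values, tolerance = 1e-12)
  expect_error(geometric_average_normalized(psths[0, ], numeric(0)),
               "eligible")
})

test_that("per-bin trace comparison flags injected differences and skips tiny samples", {
  expect_message(
    expect_null(per_bin_condition_test(matrix(1, 3, 5), matrix(1, 3, 5))),
    "skipped")
  set.seed(14)
  n_units <- 12
  n_bins <- 40
  a <- matrix(rlnorm(n_units * n_bins, 0, 0.2), n_units, n_bins)
  b <- matrix(rlnorm(n_units * n_bins, 0, 0.2), n_units, n_bins)
  inj <- 7:25
  a[, inj] <- a[, inj] * 1.8
  p <- per_bin_condition_test(a, b)
  expect_true(mean(p[inj] < 0.05) > 0.8)
  expect_true(mean(p[-inj] < 0.05) < 0.3)
  # identical data: no bin significant
  expect_true(all(per_bin_condition_test(a, a) == 1))
})

test_that("responsiveness preselection separates evoked from silent units", {
  s <- small_session()
  # every generated unit has a strong evoked response at its best frequency,
  # but take the unit whose tuning is closest to 3 kHz for a robust check
  bf_dist <- abs(log2(s$units$best_frequency / 3000))
  u_best <- s$units$unit_id[which.min(bf_dist)]
  expect_true(as.logical(is_responsive(s, u_best, 3000, n_perm = 300)))
  # an all-empty unit is never responsive
  s2 <- s
  s2$spikes <- s$spikes[0, ]
  expect_false(as.logical(is_responsive(s2, u_best, 3000, n_perm = 300)))
})

test_that("normalized response is the during/before ratio of floored means", {
  s <- small_session()
  u <- s$units$unit_id[1]
  tr <- condition_trials(s, 3000, "S1_UNCERTAIN")
  during <- unit_trial_rates(s, u, tr$trial_id, "s1", c(0, 0.25))
  before <- unit_trial_rates(s, u, tr$trial_id, "s1", c(-0.25, 0))
  manual <- max(mean(during), 0.1) / max(mean(before), 0.1)
  expect_equal(normalized_response(s, u, 3000, "S1_UNCERTAIN"), manual,
               tolerance = 1e-12)
  # not enough trials -> NA
  expect_true(is.na(normalized_response(s, u, 3000, "S1_UNCERTAIN",
                                        min_trials = 10000)))
})

test_that("best-frequency estimation recovers a unit's tuning peak", {
  expect_equal(octave_distance(3000, 3000), 0)
  expect_equal(octave_distance(6000, 3000), 1)
  expect_equal(octave_distance(1500, 3000), 1)
  # noise-free tuned unit: BF within one grid step of the true parameter
  freqs <- 2^seq(log2(62.5), log2(16000), length.out = 40)
  unit <- unit_params(best_frequency = 2000, trial_gain_sd = 0,
                      evoked_gain = 6, adaptation_strength = 0,
                      motor_ramp_amp = 0, tuning_bandwidth = 0.3)
  events <- data.frame(
    trial_id = seq_len(400), block_id = 1L, phase = "bf", task = "BF",
    matched_task = NA_character_, seq_id = NA_character_,
    s1_freq = rep(freqs, 10), s2_freq = NA_real_, t_led = NA_real_,
    t_grasp = NA_real_, t_s1 = 0.2, t_s2 = NA_real_, tone_duration = 0.1,
    t_end = 0.5, p_s1 = 1 / 40, p_s2 = NA_real_, iti = NA_real_,
    required = NA_character_, t_release = NA_real_,
    outcome = NA_character_)
  set.seed(6)
  sp <- do.call(rbind, lapply(seq_len(400), function(j) {
    tr <- as.list(events[j, ])
    times <- simulate_spike_train(build_rate_profile(unit, tr))
    if (!length(times)) return(NULL)
    data.frame(unit_id = 1L, trial_id = j, time = times)
  }))
  ses <- list(events = events, spikes = sp)
  bf <- best_frequency(ses, 1L)
  expect_true(bf$tuned)
  expect_lte(octave_distance(bf$best_frequency, 2000), 8 / 39 + 1e-9)
  # a silent unit is untuned
  ses$spikes <- sp[0, ]
  expect_false(best_frequency(ses, 1L)$tuned)
})
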