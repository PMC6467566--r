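test_that("attribution accounting reproduces its defining arithmetic", {
  a <- attribution_accounting(298, 124, 47, 63, 11)
  expect_equal(a$n_context_attributed, 22)
  expect_equal(a$n_remainder, 55)
  expect_equal(a$pct_remainder_of_sig, 44.4)
  expect_equal(a$pct_remainder_of_total, 18.5)
  b <- attribution_accounting(294, 108, 33, 48, 5)
  expect_equal(b$n_context_attributed, 11)
  expect_equal(b$n_remainder, 64)
  expect_equal(b$pct_remainder_of_sig_int, 59)
  # no confound attribution at all
  c0 <- attribution_accounting(100, 40, 0, 20, 0)
  expect_equal(c0$n_remainder, 40)
  expect_equal(c0$pct_remainder_of_sig, 100)
  # no passive data: context marked not estimable
  ne <- attribution_accounting(100, 40, 10, NA, NA)
  expect_false(ne$context_estimable)
  expect_equal(ne$n_remainder, 30)
  expect_error(attribution_accounting(100, 40, 39, 10, 9), "remainder")
  expect_error(attribution_accounting(100, 40, 50, 10, 2), "exceeds")
})

test_that("ratio summaries use the signed-rank median test correctly", {
  s <- summarize_ratios(rep(1, 10), rep(0.5, 10))
  expect_equal(s$median, 1)
  expect_equal(s$p_median, 1)
  expect_equal(s$n_significant, 0)
  s2 <- summarize_ratios(rep(2, 20), rep(0.01, 20))
  expect_equal(s2$n_significant, 20)
  expect_equal(s2$n_significant_gt1, 20)
  # order invariance
  set.seed(3)
  r <- rlnorm(15, 0.2, 0.3)
  p <- runif(15)
  perm <- sample(15)
  expect_equal(unclass(summarize_ratios(r, p)),
               unclass(summarize_ratios(r[perm], p[perm])))
  # small-n exact signed-rank against sign-enumeration oracle
  for (i in 1:5) {
    x <- exp(rnorm(7, 0.3, 0.5))
    expect_equal(summarize_ratios(x, runif(7))$p_median,
                 oracle_signed_rank_p(log(x)), tolerance = 1e-12)
  }
  expect_error(summarize_ratios(numeric(0), numeric(0)), "no ratios")
})

test_that("proportion comparisons handle sidedness and small counts", {
  expect_equal(compare_proportions(50, 100, 50, 100,
                                   alternative = "greater")$p_value, 0.5)
  # more significant during- than before-tone ratios, one-tailed
  cmp <- compare_proportions(124, 298, 88, 298, alternative = "greater")
  expect_lt(cmp$p_value, 0.05)
  # direction mismatch pushes the one-tailed p toward 1
  rev <- compare_proportions(88, 298, 124, 298, alternative = "greater")
  expect_gt(rev$p_value, 0.95)
  # chi-square approximation stays within a documented band of Fisher
  chi <- compare_proportions(8, 20, 3, 18, alternative = "greater")
  fis <- compare_proportions(8, 20, 3, 18, alternative = "greater",
                             method = "fisher")
  expect_lt(abs(log(chi$p_value / fis$p_value)), log(3))
  expect_error(compare_proportions(5, 0, 1, 10), "totals")
  expect_error(compare_proportions(11, 10, 1, 10), "exceed")
})

test_that("six-condition comparison flags injected no-go enhancement only", {
  set.seed(19)
  n <- 25
  conds <- c("S1_NO_GO", "S1_UNCERTAIN", "S2_GO", "S2_NO_GO",
             "S2_NIL_TASK2", "S2_NIL_TASK1")
  m <- matrix(rlnorm(n * 6, 0.5, 0.25), n, 6, dimnames = list(NULL, conds))
  m[, c("S1_NO_GO", "S2_NO_GO")] <- m[, c("S1_NO_GO", "S2_NO_GO")] * 1.5
  res <- six_condition_comparison(m)
  expect_equal(res$alpha_corrected, 0.0125)
  non_nogo <- c("S1_UNCERTAIN", "S2_GO", "S2_NIL_TASK2", "S2_NIL_TASK1")
  for (ng in c("S1_NO_GO", "S2_NO_GO")) {
    expect_true(all(res$p_matrix[ng, non_nogo] < 0.0125))
    expect_true(all(res$medians[ng] > res$medians[non_nogo]))
  }
  # identical conditions give p = 1
  same <- matrix(rep(m[, 1], 6), n, 6, dimnames = list(NULL, conds))
  expect_true(all(six_condition_comparison(same)$p_matrix == 1,
                  na.rm = TRUE))
  # a neutral matrix produces no significance beyond the calibration rate
  set.seed(20)
  neutral <- matrix(rlnorm(n * 6, 0.5, 0.25), n, 6,
                    dimnames = list(NULL, conds))
  pn <- six_condition_comparison(neutral)$p_matrix
  expect_lt(mean(pn < 0.0125, na.rm = TRUE), 0.2)
})

test_that("condition-label permutation destroys six-condition significance", {
  set.seed(29)
  n <- 25
  conds <- c("S1_NO_GO", "S1_UNCERTAIN", "S2_GO", "S2_NO_GO",
             "S2_NIL_TASK2", "S2_NIL_TASK1")
  m <- matrix(rlnorm(n * 6, 0.5, 0.25), n, 6, dimnames = list(NULL, conds))
  m[, c("S1_NO_GO", "S2_NO_GO")] <- m[, c("S1_NO_GO", "S2_NO_GO")] * 1.5
  # shuffle labels within each unit: the no-go structure disappears
  shuffled <- t(apply(m, 1, sample))
  colnames(shuffled) <- conds
  p <- six_condition_comparison(shuffled)$p_matrix
  expect_lt(mean(p < 0.0125, na.rm = TRUE), 0.2)
})

test_that("false-alarm contrasts apply the eligibility rules and direction", {
  # generator with frequent false alarms so per-unit FA counts exceed 5
  cfg <- session_config(n_units = 6, n_lfp_sites = 0, trials_per_block = 80,
                        n_blocks_per_task = 2, include_passive = FALSE,
                        include_bf_block = FALSE, fa_rate_s1nogo = 0.4,
                        fa_rate_s2nogo = 0.4, seed = 77)
  s <- generate_session(cfg)
  eligible <- expand.grid(unit_id = s$units$unit_id, freq = c(3000, 1000),
                          position = c("S1", "S2"),
                          stringsAsFactors = FALSE)
  fa <- false_alarm_contrast(s, eligible)
  # FA trials lack the no-go gain, so FA/correct-no-go sits below 1
  expect_lt(fa$s1_nogo_fa_vs_correct$median, 1)
  expect_gt(fa$s1_nogo_fa_vs_correct$n, 0)
  expect_lt(fa$s2_nogo_fa_vs_correct_nogo$median, 1)
  # the threshold rule excludes units with fewer than five FA trials
  fa9 <- false_alarm_contrast(s, eligible, min_fa = 10^6)
  expect_equal(fa9$s1_nogo_fa_vs_correct$n, 0)
})

test_that("probability bookkeeping and subset analysis behave as designed", {
  expect_equal(probability_ratio_summary(0.73, 0.27)$median_ratio,
               0.73 / 0.27, tolerance = 1e-12)
  pr <- probability_ratio_summary(c(0.7, 0.73, 0.8), c(0.3, 0.27, 0.2))
  expect_equal(pr$median_ratio, 0.73 / 0.27, tolerance = 1e-12)
  # contrived subsets: high-ratio sessions have more significant units
  units <- data.frame(
    session = rep(sprintf("s%d", 1:6), each = 10),
    ratio = 1.2,
    significant = c(rep(TRUE, 8), rep(FALSE, 2),   # high sessions: 80%
                    rep(TRUE, 8), rep(FALSE, 2),
                    rep(TRUE, 8), rep(FALSE, 2),
                    rep(TRUE, 2), rep(FALSE, 8),   # low sessions: 20%
                    rep(TRUE, 2), rep(FALSE, 8),
                    rep(TRUE, 2), rep(FALSE, 8)))
  probs <- data.frame(session = sprintf("s%d", 1:6),
                      p_task1 = c(0.85, 0.84, 0.83, 0.70, 0.69, 0.68),
                      p_task2 = c(0.15, 0.16, 0.17, 0.30, 0.31, 0.32))
  res <- probability_subset_analysis(units, probs)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$high$prop, res$low$prop)
  # no difference between subsets: one-tailed p at 0.5
  units$significant <- rep(c(TRUE, FALSE), 30)
  expect_equal(probability_subset_analysis(units, probs)$p_value, 0.5)
  expect_error(probability_subset_analysis(units, probs[1:2, ]),
               "2 sessions")
})

test_that("session-level subset controls mirror the adaptation logic", {
  # eight sessions spanning the admissible go fractions; session probability
  # ratios then span roughly 2-5.5
  gfs <- seq(0.50, 0.77, length.out = 8)
  run_sessions <- function(unit, seed0) {
    tabs <- list()
    probs <- list()
    for (i in seq_along(gfs)) {
      cfg <- session_config(n_units = 12, n_lfp_sites = 0,
                            trials_per_block = 140, n_blocks_per_task = 1,
                            include_passive = FALSE,
                            include_bf_block = FALSE,
                            go_fraction = gfs[i], unit = unit,
                            seed = seed0 + i)
      s <- generate_session(cfg)
      tab <- session_spike_ratios(s, freqs = 3000, positions = "S1",
                                  phases = "task", windows = "during",
                                  n_perm = 500, responsive_only = FALSE)
      tab$session <- sprintf("s%d", i)
      tabs[[i]] <- tab
      probs[[i]] <- data.frame(
        session = sprintf("s%d", i),
        p_task1 = s$schedules$p_3000[s$schedules$task == "TASK1"],
        p_task2 = s$schedules$p_3000[s$schedules$task == "TASK2"])
    }
    list(units = do.call(rbind, tabs), probs = do.call(rbind, probs))
  }
  # positive control: adaptation only -> subset difference in the
  # direction predicted by stimulus-specific adaptation
  adapt_unit <- unit_params(nogo_gain = 1, adaptation_strength = 0.3,
                            cue_offset = c(TASK1 = 0, TASK2 = 0),
                            best_frequency = 3000, motor_ramp_amp = 0)
  pos <- run_sessions(adapt_unit, 500)
  res_pos <- probability_subset_analysis(pos$units, pos$probs)
  expect_gt(res_pos$median_ratio, 2)
  expect_lt(res_pos$p_value, 0.05)
  # negative control: association effect without adaptation -> no subset
  # difference in the predicted direction
  assoc_unit <- unit_params(nogo_gain = 1.3, adaptation_strength = 0,
                            cue_offset = c(TASK1 = 0, TASK2 = 0),
                            best_frequency = 3000, motor_ramp_amp = 0)
  neg <- run_sessions(assoc_unit, 900)
  res_neg <- probability_subset_analysis(neg$units, neg$probs)
  expect_gt(res_neg$p_value, 0.05)
})
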