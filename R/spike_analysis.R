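#' Mean firing rate in a half-open window
#'
#' Spike count in `[window[1], window[2])` divided by the window length.
#' Spikes exactly at the right edge are excluded.
#'
#' @param spike_times numeric vector of spike times (s).
#' @param window numeric length-2 `[t0, t1)`, `t1 > t0`.
#' @return rate in spikes/s.
#' @examples
#' mean_rate(c(0.01, 0.1, 0.2, 0.21, 0.249), c(0, 0.25))  # 20
#' @export
mean_rate <- function(spike_times, window) {
  if (window[2] <= window[1]) stop_invalid("window must have positive length")
  sum(spike_times %inw% window) / (window[2] - window[1])
}

# Per-trial rates for one unit's spikes, aligned to an event anchor.
# `spikes` is that unit's spike table (trial_id, time); returns one rate per
# requested trial (0 for trials without spikes).
trial_rates <- function(spikes, events, trial_ids, anchor = c("s1", "s2"),
                        window = c(0, 0.25)) {
  anchor <- match.arg(anchor)
  ev_idx <- match(trial_ids, events$trial_id)
  if (anyNA(ev_idx)) stop_invalid("trial ids missing from the events table")
  t_anchor <- if (anchor == "s1") events$t_s1[ev_idx] else events$t_s2[ev_idx]
  if (anyNA(t_anchor)) stop_invalid("anchor event absent for some trials")
  sp <- spikes[spikes$trial_id %in% trial_ids, , drop = FALSE]
  pos <- match(sp$trial_id, trial_ids)
  rel <- sp$time - t_anchor[pos]
  keep <- rel >= window[1] & rel < window[2]
  counts <- tabulate(pos[keep], nbins = length(trial_ids))
  counts / (window[2] - window[1])
}

#' Per-trial window rates for a unit of a session
#'
#' @param session an `ephys_session` (or any list with `events`, `spikes`).
#' @param unit_id unit to analyse.
#' @param trial_ids trials to include.
#' @param anchor `"s1"` or `"s2"`: the tone the window is measured from.
#' @param window offsets (s) relative to the anchor, half-open.
#' @return numeric vector of rates (spikes/s), one per trial.
#' @export
unit_trial_rates <- function(session, unit_id, trial_ids,
                             anchor = c("s1", "s2"), window = c(0, 0.25)) {
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  trial_rates(sp, session$events, trial_ids, anchor, window)
}

#' Trials on which a tone of a given frequency carries a given label
#'
#' Selects the presentations of `freq` whose sensorimotor-association label
#' (computed from the block's task, or from the matched task for passive
#' blocks) equals `label`, and reports which tone (S1 or S2) to align to.
#'
#' @param session an `ephys_session`.
#' @param freq tone frequency (Hz).
#' @param label one of [CONDITION_LABELS].
#' @param task restrict to blocks of (or matched to) this task; needed to
#'   disambiguate the two S2-nil contexts.
#' @param phase `"task"` or `"passive"`.
#' @param outcomes for task phase, the admissible outcomes (default correct
#'   trials only). Use e.g. `"FALSE_ALARM"` for error-trial analyses;
#'   `NULL` disables outcome filtering.
#' @return data.frame with `trial_id` and `anchor`.
#' @export
condition_trials <- function(session, freq, label, task = NULL,
                             phase = c("task", "passive"),
                             outcomes = c("HIT", "CORRECT_REJECTION")) {
  phase <- match.arg(phase)
  label <- match.arg(label, CONDITION_LABELS)
  ev <- session$events[session$events$phase == phase, , drop = FALSE]
  if (!is.null(task)) ev <- ev[ev$matched_task == task, , drop = FALSE]
  if (phase == "task" && !is.null(outcomes)) {
    ev <- ev[ev$outcome %in% outcomes, , drop = FALSE]
  }
  position <- if (startsWith(label, "S1")) "S1" else "S2"
  out <- list()
  for (tk in unique(ev$matched_task)) {
    sub <- ev[ev$matched_task == tk, , drop = FALSE]
    if (position == "S1") {
      sel <- sub$s1_freq == freq &
        label_condition(tk, "S1", sub$s1_freq) == label
      anchor <- "s1"
    } else {
      sel <- !is.na(sub$s2_freq) & sub$s2_freq == freq &
        label_condition(tk, "S2", sub$s2_freq, sub$s1_freq) == label
      anchor <- "s2"
    }
    if (any(sel)) {
      out[[length(out) + 1L]] <- data.frame(trial_id = sub$trial_id[sel],
                                            anchor = anchor)
    }
  }
  if (length(out) == 0) {
    return(data.frame(trial_id = integer(0), anchor = character(0)))
  }
  do.call(rbind, out)
}

#' Ratio of trial-averaged rates between two conditions
#'
#' Mean-over-trials rate of the numerator condition divided by that of the
#' denominator condition, both floored at `eps` before division.
#'
#' @param rates_num,rates_den per-trial rates (spikes/s).
#' @param eps rate floor (spikes/s) applied to the two means.
#' @param min_trials minimum trials required on each side.
#' @return the ratio (dimensionless, > 0).
#' @examples
#' condition_ratio(c(10, 20, 30), c(10, 10, 10))  # 2
#' @export
condition_ratio <- function(rates_num, rates_den, eps = 0.1, min_trials = 5) {
  if (length(rates_num) < min_trials || length(rates_den) < min_trials) {
    stop_invalid("need at least %d trials per condition (got %d and %d)",
                 min_trials, length(rates_num), length(rates_den))
  }
  if (all(rates_num == 0) && all(rates_den == 0)) {
    stop_invalid("undefined ratio: unit silent in both conditions")
  }
  floor_rate(mean(rates_num), eps) / floor_rate(mean(rates_den), eps)
}

#' Permutation test for a between-condition rate ratio
#'
#' Two-sided test of the ratio of trial-averaged rates against 1. The
#' statistic is `|log(mean_a / mean_b)|` (means floored at `eps`); condition
#' labels are shuffled across the pooled trials preserving group sizes.
#' When the number of distinct assignments `choose(n, n_a)` is at most
#' `n_perm` the null distribution is enumerated exhaustively
#' (`p = #{assignments with statistic >= observed} / total`); otherwise
#' `n_perm` random reassignments are drawn and the add-one estimator
#' `p = (1 + #exceedances) / (n_perm + 1)` is used, so p is never 0.
#'
#' @param rates_a,rates_b per-trial rates of the two conditions.
#' @param n_perm random permutations (and the exhaustiveness cutoff).
#' @param eps rate floor.
#' @return list with `p_value`, `ratio` (a over b), `exact` (exhaustive?),
#'   `n_perm`.
#' @export
permutation_test_ratio <- function(rates_a, rates_b, n_perm = 1000,
                                   eps = 0.1) {
  if (length(rates_a) < 1 || length(rates_b) < 1) {
    stop_invalid("need at least one trial per side")
  }
  pooled <- c(rates_a, rates_b)
  n <- length(pooled)
  na <- length(rates_a)
  ratio <- floor_rate(mean(rates_a), eps) / floor_rate(mean(rates_b), eps)
  if (length(unique(pooled)) == 1L) {
    return(list(p_value = 1, ratio = ratio, exact = TRUE, n_perm = 0L))
  }
  stat <- function(sum_a) {
    ma <- floor_rate(sum_a / na, eps)
    mb <- floor_rate((tot - sum_a) / (n - na), eps)
    abs(log(ma / mb))
  }
  tot <- sum(pooled)
  obs <- stat(sum(rates_a))
  tol <- 1e-12
  n_comb <- choose(n, na)
  if (n_comb <= n_perm) {
    idx <- combn(n, na)
    sums <- colSums(matrix(pooled[idx], nrow = na))
    p <- mean(stat_vec(sums, na, n, tot, eps) >= obs - tol)
    return(list(p_value = p, ratio = ratio, exact = TRUE,
                n_perm = as.integer(n_comb)))
  }
  sums <- vapply(seq_len(n_perm),
                 function(i) sum(pooled[sample.int(n, na)]), 0)
  exceed <- sum(stat_vec(sums, na, n, tot, eps) >= obs - tol)
  list(p_value = (1 + exceed) / (n_perm + 1), ratio = ratio, exact = FALSE,
       n_perm = as.integer(n_perm))
}

stat_vec <- function(sum_a, na, n, tot, eps) {
  abs(log(floor_rate(sum_a / na, eps) / floor_rate((tot - sum_a) / (n - na), eps)))
}

#' Paired permutation (sign-flip) test
#'
#' Two-sided test that paired differences `x - y` have mean zero: the
#' statistic `|mean(d)|` is compared against random (or, when `2^n <=
#' n_perm`, all) sign assignments of the differences.
#'
#' @param x,y paired observations.
#' @param n_perm random flips (and the exhaustiveness cutoff).
#' @return list with `p_value`, `exact`.
#' @export
paired_permutation_test <- function(x, y, n_perm = 1000) {
  if (length(x) != length(y)) stop_invalid("x and y must be paired")
  d <- x - y
  n <- length(d)
  if (all(d == 0)) return(list(p_value = 1, exact = TRUE))
  obs <- abs(mean(d))
  tol <- 1e-12
  if (2^n <= n_perm) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    stats <- abs(signs %*% d) / n
    return(list(p_value = mean(stats >= obs - tol), exact = TRUE))
  }
  stats <- vapply(seq_len(n_perm),
                  function(i) abs(mean(d * sample(c(-1, 1), n, TRUE))), 0)
  list(p_value = (1 + sum(stats >= obs - tol)) / (n_perm + 1), exact = FALSE)
}

# during/before windows (s, relative to tone onset) for spikes
spike_windows <- function(tone_duration = 0.2) {
  len <- tone_duration + 0.05
  list(during = c(0, len), before = c(-len, 0))
}

#' Tone responsiveness of a unit
#'
#' A unit is responsive to a frequency if its rates before and during the
#' tone differ significantly (paired sign-flip permutation test, p < alpha)
#' in at least one of the four informative conditions (S1-no-go,
#' S1-uncertain, S2-no-go, S2-go), or their position-equivalents in the
#' passive phase. Conditions with fewer than `min_trials` trials are
#' skipped.
#'
#' @param session an `ephys_session`.
#' @param unit_id unit to test.
#' @param freq tone frequency (Hz).
#' @param phase `"task"` or `"passive"`.
#' @param alpha significance level.
#' @param n_perm permutations per condition test.
#' @param min_trials minimum trials per condition.
#' @return logical flag with attribute `p_values` (named per condition).
#' @export
is_responsive <- function(session, unit_id, freq, phase = "task",
                          alpha = 0.05, n_perm = 1000, min_trials = 5) {
  w <- spike_windows()
  conds <- c("S1_NO_GO", "S1_UNCERTAIN", "S2_NO_GO", "S2_GO")
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  ps <- stats::setNames(rep(NA_real_, length(conds)), conds)
  for (cond in conds) {
    tr <- condition_trials(session, freq, cond, phase = phase)
    if (nrow(tr) < min_trials) next
    before <- trial_rates(sp, session$events, tr$trial_id, tr$anchor[1],
                          w$before)
    during <- trial_rates(sp, session$events, tr$trial_id, tr$anchor[1],
                          w$during)
    ps[cond] <- paired_permutation_test(during, before, n_perm)$p_value
  }
  flag <- any(ps < alpha, na.rm = TRUE) && !all(is.na(ps))
  structure(flag, p_values = ps)
}

#' During/before condition-ratio analysis for one unit
#'
#' Computes the spike-rate ratio between the canonical condition pair at a
#' tone position (numerator S1-no-go or S2-no-go, denominator S1-uncertain
#' or S2-go) in the during window (tone onset to 50 ms after offset) or the
#' abutting before window, with a permutation p-value. Task-phase ratios
#' use correct trials only.
#'
#' @param session an `ephys_session`.
#' @param unit_id unit.
#' @param freq tone frequency (Hz).
#' @param position `"S1"` or `"S2"`.
#' @param phase `"task"` or `"passive"`.
#' @param window `"during"` or `"before"`.
#' @param alpha,n_perm,eps,min_trials analysis parameters.
#' @return one-row data.frame (`unit_id`, `freq`, `position`, `phase`,
#'   `window`, `n_num`, `n_den`, `ratio`, `p_value`, `significant`), or
#'   `NULL` when either side has fewer than `min_trials` trials.
#' @export
spike_condition_ratio <- function(session, unit_id, freq,
                                  position = c("S1", "S2"),
                                  phase = c("task", "passive"),
                                  window = c("during", "before"),
                                  alpha = 0.05, n_perm = 1000, eps = 0.1,
                                  min_trials = 5) {
  position <- match.arg(position)
  phase <- match.arg(phase)
  window <- match.arg(window)
  pair <- if (position == "S1") c("S1_NO_GO", "S1_UNCERTAIN")
          else c("S2_NO_GO", "S2_GO")
  w <- spike_windows()[[window]]
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  rates <- lapply(pair, function(cond) {
    tr <- condition_trials(session, freq, cond, phase = phase)
    if (nrow(tr) < min_trials) return(NULL)
    trial_rates(sp, session$events, tr$trial_id, tr$anchor[1], w)
  })
  if (any(vapply(rates, is.null, TRUE))) return(NULL)
  test <- permutation_test_ratio(rates[[1]], rates[[2]], n_perm, eps)
  data.frame(unit_id = unit_id, freq = freq, position = position,
             phase = phase, window = window,
             n_num = length(rates[[1]]), n_den = length(rates[[2]]),
             ratio = test$ratio, p_value = test$p_value,
             significant = test$p_value < alpha)
}

#' Baseline-normalized response of a unit to a condition
#'
#' Trial-averaged rate in the during window divided by the trial-averaged
#' rate in the abutting before window (both floored at `eps`).
#'
#' @inheritParams spike_condition_ratio
#' @param label condition label (see [CONDITION_LABELS]).
#' @param task task context (needed for the two S2-nil conditions).
#' @param outcomes outcome filter passed to [condition_trials].
#' @return scalar normalized response, or `NA` when fewer than `min_trials`
#'   trials qualify.
#' @export
normalized_response <- function(session, unit_id, freq, label, task = NULL,
                                phase = "task",
                                outcomes = c("HIT", "CORRECT_REJECTION"),
                                eps = 0.1, min_trials = 5) {
  tr <- condition_trials(session, freq, label, task = task, phase = phase,
                         outcomes = outcomes)
  if (nrow(tr) < min_trials) return(NA_real_)
  w <- spike_windows()
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  during <- trial_rates(sp, session$events, tr$trial_id, tr$anchor[1], w$during)
  before <- trial_rates(sp, session$events, tr$trial_id, tr$anchor[1], w$before)
  floor_rate(mean(during), eps) / floor_rate(mean(before), eps)
}

#' Peristimulus time histogram
#'
#' Trial-averaged rate in consecutive half-open bins.
#'
#' @param aligned_times spike times already aligned to the anchor (s).
#' @param n_trials number of trials averaged over.
#' @param bin_width bin width (s), default 0.010.
#' @param range numeric length-2 span of the histogram.
#' @return list with `bin_centers` and `rate` (spikes/s).
#' @export
psth <- function(aligned_times, n_trials, bin_width = 0.010,
                 range = c(-0.05, 1.0)) {
  breaks <- seq(range[1], range[2], by = bin_width)
  n_bins <- length(breaks) - 1L
  idx <- findInterval(aligned_times, breaks, left.open = FALSE,
                      rightmost.closed = FALSE)
  idx <- idx[aligned_times >= range[1] & aligned_times < breaks[n_bins + 1L]]
  counts <- tabulate(idx, nbins = n_bins)
  list(bin_centers = breaks[-length(breaks)] + bin_width / 2,
       rate = counts / (n_trials * bin_width))
}

#' PSTH of one unit over a set of trials
#'
#' @param session an `ephys_session`.
#' @param unit_id unit.
#' @param trials data.frame from [condition_trials] (`trial_id`, `anchor`).
#' @param bin_width,range as in [psth].
#' @return list with `bin_centers`, `rate`, `n_trials`, `baseline` (mean
#'   rate in the 250 ms before the anchor).
#' @export
unit_psth <- function(session, unit_id, trials, bin_width = 0.010,
                      range = c(-0.05, 1.0)) {
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  ev_idx <- match(trials$trial_id, session$events$trial_id)
  t_anchor <- if (trials$anchor[1] == "s1") session$events$t_s1[ev_idx]
              else session$events$t_s2[ev_idx]
  sp <- sp[sp$trial_id %in% trials$trial_id, , drop = FALSE]
  rel <- sp$time - t_anchor[match(sp$trial_id, trials$trial_id)]
  h <- psth(rel, nrow(trials), bin_width, range)
  before <- trial_rates(sp, session$events, trials$trial_id,
                        trials$anchor[1], c(-0.25, 0))
  c(h, list(n_trials = nrow(trials), baseline = mean(before)))
}

#' Geometric-mean baseline-normalized population trace
#'
#' Each unit's per-bin rate is divided by its baseline (both floored at
#' `eps`); the population trace is the geometric mean across units:
#' `exp(mean over units of log(floored rate / floored baseline))` per bin.
#'
#' @param psths units x bins matrix of trial-averaged rates (spikes/s).
#' @param baselines per-unit baseline rates (spikes/s).
#' @param bin_centers optional bin centers carried through.
#' @param eps rate floor.
#' @return list of class `normalized_trace`: `bin_centers`, `values`,
#'   `n_units`.
#' @export
geometric_average_normalized <- function(psths, baselines,
                                         bin_centers = NULL, eps = 0.1) {
  psths <- as.matrix(psths)
  if (nrow(psths) == 0) stop_invalid("no eligible units for the trace")
  if (length(baselines) != nrow(psths)) {
    stop_invalid("one baseline per unit required")
  }
  norm <- log(floor_rate(psths, eps) / floor_rate(baselines, eps))
  structure(list(bin_centers = bin_centers,
                 values = exp(colMeans(norm)),
                 n_units = nrow(psths)),
            class = "normalized_trace")
}

#' Per-bin paired comparison of two normalized population traces
#'
#' Two-sided Wilcoxon signed-rank test per 10-ms bin on the units' paired
#' normalized rates, uncorrected. Requires at least `min_units` units.
#'
#' @param norm_a,norm_b units x bins matrices of normalized rates (same
#'   units, same bins).
#' @param min_units minimum number of units (default 6); below it the test
#'   is skipped and `NULL` returned with a message.
#' @return numeric vector of per-bin p-values, or `NULL`.
#' @export
per_bin_condition_test <- function(norm_a, norm_b, min_units = 6) {
  norm_a <- as.matrix(norm_a)
  norm_b <- as.matrix(norm_b)
  stopifnot(all(dim(norm_a) == dim(norm_b)))
  if (nrow(norm_a) < min_units) {
    message(sprintf("per-bin test skipped: %d units < %d required",
                    nrow(norm_a), min_units))
    return(NULL)
  }
  vapply(seq_len(ncol(norm_a)), function(j) {
    a <- norm_a[, j]; b <- norm_b[, j]
    if (all(a == b)) return(1)
    suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
  }, 0)
}

#' Best frequency from the 40-tone tuning block
#'
#' The best frequency is the tone maximizing the baseline-subtracted evoked
#' rate (evoked window `[0, 150 ms)` after tone onset; baseline the 150 ms
#' directly before). Units with no tone evoking a positive response are
#' flagged untuned (`NA` best frequency).
#'
#' @param session an `ephys_session` whose events include a `"bf"` phase.
#' @param unit_id unit.
#' @return list with `best_frequency` (Hz or `NA`), `tuned` (logical), and
#'   `tuning` (data.frame: `freq`, `evoked`).
#' @export
best_frequency <- function(session, unit_id) {
  ev <- session$events[session$events$phase == "bf", , drop = FALSE]
  if (nrow(ev) == 0) stop_invalid("session has no best-frequency block")
  sp <- session$spikes[session$spikes$unit_id == unit_id, , drop = FALSE]
  during <- trial_rates(sp, session$events, ev$trial_id, "s1", c(0, 0.15))
  before <- trial_rates(sp, session$events, ev$trial_id, "s1", c(-0.15, 0))
  evoked <- tapply(during - before, ev$s1_freq, mean)
  tuning <- data.frame(freq = as.numeric(names(evoked)),
                       evoked = as.numeric(evoked))
  if (max(tuning$evoked) <= 0) {
    return(list(best_frequency = NA_real_, tuned = FALSE, tuning = tuning))
  }
  list(best_frequency = tuning$freq[which.max(tuning$evoked)], tuned = TRUE,
       tuning = tuning)
}

#' Distance between two frequencies in octaves
#'
#' @param f,ref frequencies in Hz.
#' @return `|log2(f / ref)|`.
#' @examples
#' octave_distance(6000, 3000)  # 1
#' @export
octave_distance <- function(f, ref) {
  abs(log2(f / ref))
}
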