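lfp_sample_times <- function(n, fs, t0) {
  t0 + (seq_len(n) - 1) / fs
}

#' Root-mean-square of an LFP segment
#'
#' `sqrt(mean(x^2))` over the samples whose timestamps fall in the
#' half-open `window`.
#'
#' @param samples numeric vector (mV).
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample (s).
#' @param window numeric length-2 `[t0, t1)` in the same time base.
#' @return RMS in mV.
#' @examples
#' lfp_rms(c(3, -4), fs = 2, t0 = 0, window = c(0, 1))  # sqrt(12.5)
#' @export
lfp_rms <- function(samples, fs, t0, window) {
  t <- lfp_sample_times(length(samples), fs, t0)
  if (window[1] < t[1] - 1e-9 || window[2] > t[length(t)] + 1 / fs + 1e-9) {
    stop_invalid("window [%g, %g) not covered by the trace", window[1],
                 window[2])
  }
  sel <- t %inw% window
  sqrt(mean(samples[sel]^2))
}

# during/before windows (s, relative to tone onset) for LFP
lfp_windows <- function() {
  list(during = c(0, 0.5), before = c(-0.5, 0))
}

#' RMS-LFP condition ratio with a permutation test
#'
#' The RMS is computed on the trial-averaged evoked potential of each
#' condition (averaging first suppresses non-phase-locked noise); the ratio
#' is numerator RMS over denominator RMS. The permutation test reassigns
#' trials between the conditions (preserving group sizes), regenerates the
#' two trial averages, and recomputes `|log ratio|`; exhaustive enumeration
#' is used when feasible, otherwise the add-one estimator.
#'
#' @param traces_num,traces_den trials x samples matrices, same time base.
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample relative to the tone onset (s).
#' @param window analysis window relative to tone onset.
#' @param n_perm permutations.
#' @param per_trial if `TRUE`, compute per-trial RMS first and ratio the
#'   trial means instead (variant behind a flag).
#' @return list with `ratio`, `p_value`, `n_num`, `n_den`, `exact`.
#' @export
lfp_condition_ratio <- function(traces_num, traces_den, fs, t0,
                                window = c(0, 0.5), n_perm = 1000,
                                per_trial = FALSE) {
  traces_num <- as.matrix(traces_num)
  traces_den <- as.matrix(traces_den)
  n1 <- nrow(traces_num)
  n2 <- nrow(traces_den)
  if (n1 < 1 || n2 < 1) stop_invalid("need at least one trial per side")
  t <- lfp_sample_times(ncol(traces_num), fs, t0)
  sel <- t %inw% window
  if (!any(sel)) stop_invalid("window outside trace support")
  a <- traces_num[, sel, drop = FALSE]
  b <- traces_den[, sel, drop = FALSE]
  rms_of <- if (per_trial) {
    function(m) mean(sqrt(rowMeans(m^2)))
  } else {
    function(m) sqrt(mean(colMeans(m)^2))
  }
  den_rms <- rms_of(b)
  if (den_rms == 0) stop_invalid("undefined ratio: zero denominator RMS")
  obs_ratio <- rms_of(a) / den_rms
  pooled <- rbind(a, b)
  n <- n1 + n2
  obs <- abs(log(obs_ratio))
  tol <- 1e-12
  n_comb <- choose(n, n1)
  exact <- n_comb <= n_perm
  assign_mat <- if (exact) {
    # one row per assignment, binary membership of the numerator group
    idx <- combn(n, n1)
    m <- matrix(0, ncol(idx), n)
    m[cbind(rep(seq_len(ncol(idx)), each = n1), as.vector(idx))] <- 1
    m
  } else {
    m <- matrix(0, n_perm, n)
    picks <- vapply(seq_len(n_perm), function(i) sample.int(n, n1),
                    integer(n1))
    m[cbind(rep(seq_len(n_perm), each = n1), as.vector(picks))] <- 1
    m
  }
  if (per_trial) {
    # statistic on per-trial RMS values
    v <- sqrt(rowMeans(pooled^2))
    sums <- as.vector(assign_mat %*% v)
    tot <- sum(v)
    stats <- abs(log((sums / n1) / ((tot - sums) / n2)))
  } else {
    # RMS of the regenerated trial averages via the Gram matrix:
    # sum_t mean_A(x)_t^2 = (1_A' G 1_A) / n1^2 with G = X X'
    g <- tcrossprod(pooled)
    ag <- assign_mat %*% g
    q_a <- rowSums(ag * assign_mat)
    # complement quadratic form from totals: (1-a)'G(1-a) = T - 2 a's + a'Ga
    s <- rowSums(g)
    tot_q <- sum(s)
    q_b <- tot_q - 2 * as.vector(assign_mat %*% s) + q_a
    stats <- 0.5 * abs(log((q_a / n1^2) / (q_b / n2^2)))
    stats[q_a == 0 | q_b == 0] <- Inf
  }
  if (exact) {
    p <- mean(stats >= obs - tol)
  } else {
    p <- (1 + sum(stats >= obs - tol)) / (n_perm + 1)
  }
  list(ratio = obs_ratio, p_value = p, n_num = n1, n_den = n2, exact = exact)
}

# Extract a site's trials x samples matrix for given trial ids, re-based so
# that time 0 is the anchor tone onset of each trial.
site_condition_traces <- function(session, site_idx, trials) {
  site <- session$lfp[[site_idx]]
  rows <- match(trials$trial_id, site$trial_ids)
  if (anyNA(rows)) stop_invalid("trials missing from the LFP container")
  ev_idx <- match(trials$trial_id, session$events$trial_id)
  t_anchor <- if (trials$anchor[1] == "s1") session$events$t_s1[ev_idx]
              else session$events$t_s2[ev_idx]
  # all trials share timing within a session, so a common re-base applies
  offset <- t_anchor[1] - site$t0
  list(data = site$data[rows, , drop = FALSE],
       fs = site$sampling_rate, t0 = -offset)
}

#' RMS-LFP condition ratio for one site of a session
#'
#' Canonical pairs as for spikes: S1-no-go vs S1-uncertain at S1, S2-no-go
#' vs S2-go at S2; during window `[0, 500 ms)` after tone onset, before
#' window the abutting 500 ms.
#'
#' @param session an `ephys_session` with LFP data.
#' @param site_idx index into `session$lfp`.
#' @param freq tone frequency (Hz).
#' @param position `"S1"` or `"S2"`.
#' @param phase `"task"` or `"passive"`.
#' @param window `"during"` or `"before"`.
#' @param alpha,n_perm,min_trials analysis parameters.
#' @return one-row data.frame mirroring [spike_condition_ratio], or `NULL`
#'   if either side has fewer than `min_trials` trials.
#' @export
site_lfp_ratio <- function(session, site_idx, freq,
                           position = c("S1", "S2"),
                           phase = c("task", "passive"),
                           window = c("during", "before"),
                           alpha = 0.05, n_perm = 1000, min_trials = 5) {
  position <- match.arg(position)
  phase <- match.arg(phase)
  window <- match.arg(window)
  pair <- if (position == "S1") c("S1_NO_GO", "S1_UNCERTAIN")
          else c("S2_NO_GO", "S2_GO")
  w <- lfp_windows()[[window]]
  tr <- lapply(pair, function(cond)
    condition_trials(session, freq, cond, phase = phase))
  if (any(vapply(tr, nrow, 0L) < min_trials)) return(NULL)
  num <- site_condition_traces(session, site_idx, tr[[1]])
  den <- site_condition_traces(session, site_idx, tr[[2]])
  res <- lfp_condition_ratio(num$data, den$data, num$fs, num$t0, w, n_perm)
  data.frame(site_id = session$lfp[[site_idx]]$site_id, freq = freq,
             position = position, phase = phase, window = window,
             n_num = res$n_num, n_den = res$n_den, ratio = res$ratio,
             p_value = res$p_value, significant = res$p_value < alpha)
}

#' Tone responsiveness of an LFP site
#'
#' Paired sign-flip permutation test of per-trial RMS before vs during the
#' tone (500 ms windows) in each of the four informative conditions;
#' responsive if any p < alpha.
#'
#' @inheritParams site_lfp_ratio
#' @return logical flag with attribute `p_values`.
#' @export
is_responsive_lfp <- function(session, site_idx, freq, phase = "task",
                              alpha = 0.05, n_perm = 1000, min_trials = 5) {
  w <- lfp_windows()
  conds <- c("S1_NO_GO", "S1_UNCERTAIN", "S2_NO_GO", "S2_GO")
  ps <- stats::setNames(rep(NA_real_, length(conds)), conds)
  for (cond in conds) {
    tr <- condition_trials(session, freq, cond, phase = phase)
    if (nrow(tr) < min_trials) next
    tc <- site_condition_traces(session, site_idx, tr)
    t <- lfp_sample_times(ncol(tc$data), tc$fs, tc$t0)
    rms_d <- sqrt(rowMeans(tc$data[, t %inw% w$during, drop = FALSE]^2))
    rms_b <- sqrt(rowMeans(tc$data[, t %inw% w$before, drop = FALSE]^2))
    ps[cond] <- paired_permutation_test(rms_d, rms_b, n_perm)$p_value
  }
  flag <- any(ps < alpha, na.rm = TRUE) && !all(is.na(ps))
  structure(flag, p_values = ps)
}

#' Baseline-normalized geometric-mean RMS-LFP trace
#'
#' For each site, the RMS of the trial-averaged potential is computed in
#' consecutive 10-ms bins from 500 ms before tone onset to 800 ms after
#' tone offset; each bin is normalized to the mean RMS over the 500 ms
#' before tone onset, and the normalized traces are geometrically averaged
#' across sites. Scale-invariant per site (amplifier gain drops out).
#'
#' @param traces list of per-site trials x samples matrices (same fs/t0).
#' @param fs sampling rate (Hz).
#' @param t0 time of the first sample relative to tone onset (s).
#' @param tone_offset tone offset time (s after onset), default 0.2.
#' @param bin_width bin width (s).
#' @param eps floor for the per-bin RMS (mV) before logs.
#' @return `normalized_trace` (see [geometric_average_normalized]).
#' @export
normalized_lfp_trace <- function(traces, fs, t0, tone_offset = 0.2,
                                 bin_width = 0.010, eps = 1e-9) {
  span <- c(-0.5, tone_offset + 0.8)
  breaks <- seq(span[1], span[2], by = bin_width)
  n_bins <- length(breaks) - 1L
  per_site <- vapply(traces, function(m) {
    m <- as.matrix(m)
    t <- lfp_sample_times(ncol(m), fs, t0)
    avg <- colMeans(m)
    idx <- findInterval(t, breaks, left.open = FALSE)
    sel <- t >= span[1] & t < breaks[n_bins + 1L]
    bin_rms <- vapply(seq_len(n_bins), function(b) {
      s <- sel & idx == b
      if (!any(s)) return(NA_real_)
      sqrt(mean(avg[s]^2))
    }, 0)
    base <- mean(bin_rms[breaks[-length(breaks)] < 0], na.rm = TRUE)
    if (!is.finite(base) || base == 0) return(rep(NA_real_, n_bins))
    pmax(bin_rms, eps) / pmax(base, eps)
  }, numeric(n_bins))
  per_site <- t(per_site)  # sites x bins
  ok <- apply(per_site, 1, function(r) all(is.finite(r)))
  if (!any(ok)) stop_invalid("no site with a usable baseline RMS")
  if (any(!ok)) message(sprintf("%d site(s) excluded (zero baseline RMS)",
                                sum(!ok)))
  vals <- exp(colMeans(log(per_site[ok, , drop = FALSE])))
  structure(list(bin_centers = breaks[-length(breaks)] + bin_width / 2,
                 values = vals, n_units = sum(ok)),
            class = "normalized_trace")
}
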