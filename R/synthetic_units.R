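#' Parameters of a simulated unit
#'
#' Describes one multiunit's firing model. The tone-evoked elevation is
#' `baseline_rate * (evoked_gain - 1)`, gated by a Gaussian frequency-tuning
#' curve on a log2 axis, scaled down by stimulus-specific adaptation
#' (proportional to the tone's probability in its block) and, for an S2
#' repeating S1's frequency, by forward suppression. When a tone's label is
#' a no-go association, the whole rate is multiplied by `nogo_gain` from
#' `nogo_onset` after tone onset to the end of the evoked window -- except
#' on false-alarm trials, where the modulation is withheld (the neural
#' response tracks what the subject did, not what it should have done).
#' Trials with a bar release get a triangular pre-release motor ramp.
#'
#' @param baseline_rate spontaneous rate, spikes/s (> 0).
#' @param best_frequency Hz.
#' @param tuning_bandwidth Gaussian tuning SD in octaves.
#' @param evoked_gain multiplier on baseline at the best frequency (> 0).
#' @param nogo_gain multiplicative rate gain for no-go-labelled tones (> 0).
#' @param cue_offset named numeric `c(TASK1 = , TASK2 = )`, additive tonic
#'   rate shift (spikes/s) present throughout trials of each task (the
#'   visual-cue confound). Absent in passive blocks.
#' @param adaptation_strength in `[0, 1]`; evoked response is scaled by
#'   `1 - adaptation_strength * p` where `p` is the tone's frequency
#'   probability in the block.
#' @param forward_suppression in `[0, 1]`; S2 evoked response is scaled by
#'   `1 - forward_suppression` when S2 repeats S1's frequency.
#' @param motor_ramp_amp peak of the pre-release ramp, spikes/s.
#' @param trial_gain_sd SD (log scale) of a per-trial lognormal gain shared
#'   by the whole trial, modelling slow excitability fluctuations.
#' @param nogo_onset latency (s) at which the no-go differential switches
#'   on after tone onset.
#' @param ramp_onset,ramp_peak seconds before bar release at which the
#'   motor ramp starts and peaks.
#' @return object of class `unit_params`.
#' @export
unit_params <- function(baseline_rate = 20, best_frequency = 3000,
                        tuning_bandwidth = 1.5, evoked_gain = 3,
                        nogo_gain = 1.3,
                        cue_offset = c(TASK1 = 0, TASK2 = 1),
                        adaptation_strength = 0.15,
                        forward_suppression = 0.3,
                        motor_ramp_amp = 15,
                        trial_gain_sd = 0.25,
                        nogo_onset = 0.07,
                        ramp_onset = 0.3, ramp_peak = 0.2) {
  if (baseline_rate <= 0) stop_invalid("baseline_rate must be > 0")
  if (evoked_gain <= 0 || nogo_gain <= 0) stop_invalid("gains must be > 0")
  if (adaptation_strength < 0 || adaptation_strength > 1 ||
      forward_suppression < 0 || forward_suppression > 1) {
    stop_invalid("adaptation_strength and forward_suppression must be in [0, 1]")
  }
  stopifnot(all(c("TASK1", "TASK2") %in% names(cue_offset)))
  structure(as.list(environment()), class = "unit_params")
}

#' Parameters of a simulated LFP site
#'
#' The evoked potential per tone is the sum of two Gaussian-envelope
#' deflections (amplitude in mV, negative for the canonical downward
#' deflections); the second deflection is scaled by `nogo_gain` when the
#' tone carries a no-go label (withheld on false alarms, as for spikes).
#' Additive noise is Gaussian with power ~ 1/f^`noise_exponent`,
#' band-limited to `band`.
#'
#' @param sampling_rate Hz (>= 200).
#' @param amplitude,latency,width length-2 vectors: per-deflection peak
#'   amplitude (mV), latency of the peak after tone onset (s, inside
#'   `[0, 0.5]`), and Gaussian envelope SD (s).
#' @param nogo_gain multiplier on the second deflection for no-go labels.
#' @param noise_sd noise standard deviation, mV.
#' @param noise_exponent spectral exponent (1 = pink noise).
#' @param band passband in Hz for the noise.
#' @return object of class `lfp_params`.
#' @export
lfp_params <- function(sampling_rate = 1000,
                       amplitude = c(-0.12, -0.08),
                       latency = c(0.05, 0.15),
                       width = c(0.015, 0.04),
                       nogo_gain = 1.5,
                       noise_sd = 0.05,
                       noise_exponent = 1,
                       band = c(1, 140)) {
  if (sampling_rate < 200) stop_invalid("sampling_rate must be >= 200 Hz")
  if (any(latency < 0 | latency > 0.5)) {
    stop_invalid("deflection latencies must lie in [0, 0.5] s")
  }
  structure(as.list(environment()), class = "lfp_params")
}

# Gaussian tuning on a log2 frequency axis.
tuning_factor <- function(unit, freq) {
  exp(-0.5 * ((log2(freq) - log2(unit$best_frequency)) / unit$tuning_bandwidth)^2)
}

#' Closed-form firing-rate profile for one unit on one trial
#'
#' Builds the piecewise (linear) rate function described in [unit_params]:
#' baseline + cue offset, tone-evoked elevations over
#' `[onset, onset + duration + 0.05)`, the no-go gain window, and the motor
#' ramp. Negative intermediate rates are clipped at zero.
#'
#' @param unit a [unit_params].
#' @param trial a list (or one-row data.frame) with fields `task`
#'   (`"TASK1"`/`"TASK2"` for task trials, anything else for passive),
#'   `phase` (`"task"`, `"passive"`, `"bf"`), `s1_freq`, `s2_freq` (may be
#'   `NA` for single-tone presentations), `t_s1`, `t_s2` (`NA` if none),
#'   `tone_duration`, `t_release` (`NA` if no release), `outcome` (`NA` in
#'   passive), `p_s1`, `p_s2` (frequency probabilities of each tone in its
#'   block context), `t_end` (trial duration).
#' @param gain extra multiplicative factor applied to the whole profile
#'   (the per-trial excitability gain; default 1).
#' @return object of class `rate_profile`: list with `fn` (vectorised rate
#'   function of trial time, spikes/s), `t_end`, and `sup` (a finite upper
#'   bound on the rate, used for thinning).
#' @export
build_rate_profile <- function(unit, trial, gain = 1) {
  trial <- as.list(trial)
  is_task <- identical(trial$phase, "task")
  base <- unit$baseline_rate +
    if (is_task) unname(unit$cue_offset[trial$task]) else 0

  dur_ev <- trial$tone_duration + 0.05
  tones <- list()
  add_tone <- function(onset, freq, p, fwd, label) {
    amp <- unit$baseline_rate * (unit$evoked_gain - 1) *
      tuning_factor(unit, freq) *
      (1 - unit$adaptation_strength * p) * fwd
    list(window = c(onset, onset + dur_ev), amp = amp, label = label)
  }
  lab1 <- lab2 <- NA_character_
  if (is_task) {
    lab1 <- label_condition(trial$task, "S1", trial$s1_freq)
    if (!is.na(trial$s2_freq)) {
      lab2 <- label_condition(trial$task, "S2", trial$s2_freq, trial$s1_freq)
    }
  }
  tones[[1]] <- add_tone(trial$t_s1, trial$s1_freq, trial$p_s1, 1, lab1)
  if (!is.na(trial$t_s2) && !is.na(trial$s2_freq)) {
    fwd <- if (trial$s2_freq == trial$s1_freq) 1 - unit$forward_suppression else 1
    tones[[2]] <- add_tone(trial$t_s2, trial$s2_freq, trial$p_s2, fwd, lab2)
  }

  # no-go gain windows; withheld on false alarms
  apply_nogo <- is_task && !identical(trial$outcome, "FALSE_ALARM")
  nogo_windows <- list()
  if (apply_nogo) {
    for (tn in tones) {
      if (!is.na(tn$label) && tn$label %in% c("S1_NO_GO", "S2_NO_GO")) {
        nogo_windows[[length(nogo_windows) + 1L]] <-
          c(tn$window[1] + unit$nogo_onset, tn$window[2])
      }
    }
  }

  # triangular motor ramp anchored to the release
  ramp <- NULL
  if (!is.null(trial$t_release) && !is.na(trial$t_release) &&
      unit$motor_ramp_amp > 0) {
    r <- trial$t_release
    ramp <- list(x = c(r - unit$ramp_onset, r - unit$ramp_peak, r + 0.05),
                 y = c(0, unit$motor_ramp_amp, 0))
  }

  fn <- function(t) {
    rate <- rep(base, length(t))
    for (tn in tones) {
      rate <- rate + tn$amp * (t %inw% tn$window)
    }
    mult <- rep(1, length(t))
    for (w in nogo_windows) {
      mult[t %inw% w] <- unit$nogo_gain
    }
    rate <- rate * mult
    if (!is.null(ramp)) {
      inside <- t >= ramp$x[1] & t < ramp$x[3]
      if (any(inside)) {
        rate[inside] <- rate[inside] +
          stats::approx(ramp$x, ramp$y, xout = t[inside], rule = 2)$y
      }
    }
    pmax(gain * rate, 0)
  }

  sup <- gain * (max(unit$nogo_gain, 1) *
                   (base + sum(vapply(tones, function(tn) max(tn$amp, 0), 0))) +
                   unit$motor_ramp_amp)
  structure(list(fn = fn, t_end = trial$t_end, sup = sup),
            class = "rate_profile")
}

#' Sample an inhomogeneous-Poisson spike train by thinning
#'
#' Draws candidate events from a homogeneous Poisson process at the
#' profile's supremum over `[0, t_end)` and keeps each with probability
#' `rate(t) / sup`. Uses the current RNG state; reproducible under a fixed
#' seed.
#'
#' @param profile a [build_rate_profile()] result (or any list with `fn`,
#'   `t_end`, `sup`).
#' @return sorted numeric vector of spike times (s, trial-relative).
#' @export
simulate_spike_train <- function(profile) {
  if (!is.finite(profile$sup) || profile$sup < 0) {
    stop_invalid("rate profile must have a finite nonnegative supremum")
  }
  if (profile$sup == 0) return(numeric(0))
  n_cand <- rpois(1, profile$sup * profile$t_end)
  if (n_cand == 0) return(numeric(0))
  t_cand <- sort(runif(n_cand, 0, profile$t_end))
  keep <- runif(n_cand) < profile$fn(t_cand) / profile$sup
  t_cand[keep]
}

#' Band-limited 1/f^a Gaussian noise
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param sd target standard deviation.
#' @param exponent spectral exponent a (power ~ 1/f^a).
#' @param band passband (Hz).
#' @return numeric vector of length `n`.
#' @keywords internal
colored_noise <- function(n, fs, sd = 1, exponent = 1, band = c(1, 140)) {
  if (sd == 0) return(numeric(n))
  white <- rnorm(n)
  spec <- fft(white)
  freq <- c(0, seq_len(n - 1)) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided
  scale <- ifelse(freq >= band[1] & freq <= band[2],
                  1 / pmax(freq, band[1])^(exponent / 2), 0)
  x <- Re(fft(spec * scale, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}

#' Simulate one trial's LFP trace at one site
#'
#' Sum of the per-tone evoked deflections described in [lfp_params] plus
#' band-limited 1/f noise. Samples cover `[t0, t0 + n/fs)` in trial time.
#'
#' @param params an [lfp_params].
#' @param trial trial descriptor as in [build_rate_profile].
#' @param t0 trial-relative time of the first sample.
#' @param duration trace duration in seconds.
#' @return list with `samples` (mV), `sampling_rate`, `t0`.
#' @export
simulate_lfp <- function(params, trial, t0 = trial$t_s1 - 0.6,
                         duration = 2.7) {
  trial <- as.list(trial)
  fs <- params$sampling_rate
  n <- round(duration * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  x <- colored_noise(n, fs, params$noise_sd, params$noise_exponent,
                     params$band)
  is_task <- identical(trial$phase, "task")
  apply_nogo <- is_task && !identical(trial$outcome, "FALSE_ALARM")
  add_tone <- function(x, onset, label) {
    for (i in seq_along(params$amplitude)) {
      a <- params$amplitude[i]
      if (i == 2 && apply_nogo && !is.na(label) &&
          label %in% c("S1_NO_GO", "S2_NO_GO")) {
        a <- a * params$nogo_gain
      }
      x <- x + a * exp(-0.5 * ((t - onset - params$latency[i]) /
                                 params$width[i])^2)
    }
    x
  }
  lab1 <- lab2 <- NA_character_
  if (is_task) {
    lab1 <- label_condition(trial$task, "S1", trial$s1_freq)
    if (!is.na(trial$s2_freq)) {
      lab2 <- label_condition(trial$task, "S2", trial$s2_freq, trial$s1_freq)
    }
  }
  x <- add_tone(x, trial$t_s1, lab1)
  if (!is.na(trial$t_s2) && !is.na(trial$s2_freq)) {
    x <- add_tone(x, trial$t_s2, lab2)
  }
  list(samples = x, sampling_rate = fs, t0 = t0)
}
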