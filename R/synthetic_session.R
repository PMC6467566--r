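SEQUENCES <- data.frame(
  seq_id = c("3-3", "3-1", "1-3", "1-1"),
  s1_freq = c(3000, 3000, 1000, 1000),
  s2_freq = c(3000, 1000, 3000, 1000),
  stringsAsFactors = FALSE
)

#' Sequence-probability schedule for one task block
#'
#' The go sequence gets probability `go_fraction`; the remaining mass is
#' split equally across the three no-go sequences (the default study
#' structure, which puts the go tone's frequency at probability
#' `go_fraction + (1 - go_fraction)/3` per tone slot, e.g. 0.733 at a go
#' fraction of 0.60).
#'
#' @param task_id `"TASK1"` or `"TASK2"`.
#' @param go_fraction probability of the go sequence, in `[0.50, 0.77]`.
#' @return named numeric over the four sequence ids, summing to 1.
#' @export
sequence_schedule <- function(task_id, go_fraction = 0.60) {
  if (go_fraction < 0.50 || go_fraction > 0.77) {
    stop_invalid("go_fraction must lie in [0.50, 0.77], got %g", go_fraction)
  }
  go_seq <- if (task_id == "TASK1") "3-3" else "1-1"
  p <- rep((1 - go_fraction) / 3, 4)
  names(p) <- SEQUENCES$seq_id
  p[go_seq] <- go_fraction
  p
}

#' Per-frequency tone probabilities implied by a sequence schedule
#'
#' Probability that a tone slot (S1 or S2 pooled) carries each frequency.
#'
#' @param schedule named probability vector from [sequence_schedule].
#' @return named numeric `c("1000" = , "3000" = )`.
#' @export
tone_probabilities <- function(schedule) {
  if (abs(sum(schedule) - 1) > 1e-8) {
    stop_invalid("sequence schedule must sum to 1")
  }
  p3 <- schedule[["3-3"]] + (schedule[["3-1"]] + schedule[["1-3"]]) / 2
  c("1000" = 1 - p3, "3000" = p3)
}

#' Configuration of a synthetic session
#'
#' Defaults encode the study conditions the generator emulates: alternating
#' task blocks of ~140 trials, go required in 60% of trials, false-alarm
#' rates of 0.16 (sequences where S1 signals no-go) and 0.05 (sequences
#' where S2 signals no-go), matched passive blocks reusing the two
#' probability schedules, and a 40-tone best-frequency block (8 octaves,
#' 0.0625-16 kHz, 10 repetitions, 100 ms tones).
#'
#' @param n_blocks_per_task task blocks per task (alternating order).
#' @param trials_per_block trials in each task or passive block.
#' @param go_fraction fraction of go-required trials per block (exact under
#'   the stratified scheme), admissible range 0.50-0.77.
#' @param go_fraction_jitter half-width of a per-block uniform jitter on
#'   `go_fraction` (0 = exact fraction in every block).
#' @param fa_rate_s1nogo,fa_rate_s2nogo false-alarm probability on no-go
#'   trials whose S1 (respectively only S2) signals the no-go response.
#' @param miss_rate miss probability on go trials.
#' @param n_units number of simulated multiunits.
#' @param n_lfp_sites number of simulated LFP sites (0 disables LFP).
#' @param include_passive include the two matched passive blocks.
#' @param include_bf_block include the best-frequency tuning block.
#' @param response_window go response window (s after S2 offset).
#' @param s1_onset,tone_duration,stimulus_onset_interval trial timing (s).
#' @param unit a [unit_params] used as the population mean; per-unit
#'   parameters are drawn around it (see `bf_range`, `baseline_sdlog`,
#'   `nogo_gain_sdlog`).
#' @param lfp an [lfp_params] shared by sites up to an amplitude jitter.
#' @param bf_range range (Hz) of the log-uniform best-frequency draw.
#' @param baseline_sdlog lognormal SD of per-unit baseline rates.
#' @param nogo_gain_sdlog lognormal SD of per-unit no-go gains (0 = all
#'   units share `unit$nogo_gain`).
#' @param seed master RNG seed; all randomness derives from it through
#'   per-unit/per-trial substreams.
#' @return object of class `session_config`.
#' @export
session_config <- function(n_blocks_per_task = 2,
                           trials_per_block = 140,
                           go_fraction = 0.60,
                           go_fraction_jitter = 0,
                           fa_rate_s1nogo = 0.16,
                           fa_rate_s2nogo = 0.05,
                           miss_rate = 0.05,
                           n_units = 16,
                           n_lfp_sites = 4,
                           include_passive = TRUE,
                           include_bf_block = TRUE,
                           response_window = c(0.04, 1.16),
                           s1_onset = 1.0,
                           tone_duration = 0.2,
                           stimulus_onset_interval = 1.0,
                           unit = unit_params(),
                           lfp = lfp_params(),
                           bf_range = c(500, 8000),
                           baseline_sdlog = 0.25,
                           nogo_gain_sdlog = 0,
                           seed = 1L) {
  sequence_schedule("TASK1", go_fraction)  # validates range
  if (any(c(fa_rate_s1nogo, fa_rate_s2nogo, miss_rate) < 0 |
            c(fa_rate_s1nogo, fa_rate_s2nogo, miss_rate) > 1)) {
    stop_invalid("rates must lie in [0, 1]")
  }
  if (n_units < 1) stop_invalid("n_units must be >= 1")
  structure(as.list(environment()), class = "session_config")
}

# Stratified block contents: exact (possibly jittered) go count, remaining
# trials split as evenly as possible over the no-go sequences (ties broken
# at random), then permuted.
block_sequences <- function(schedule, n, go_seq) {
  n_go <- round(schedule[[go_seq]] * n)
  nogo <- setdiff(names(schedule), go_seq)
  rest <- n - n_go
  counts <- stats::setNames(rep(rest %/% 3, 3), nogo)
  rem <- rest %% 3
  if (rem > 0) {
    bump <- sample(nogo, rem)
    counts[bump] <- counts[bump] + 1L
  }
  counts[go_seq] <- n_go
  ids <- rep(names(counts), counts)
  sample(ids)
}

#' Generate a complete synthetic session
#'
#' Produces alternating task blocks, optional matched passive blocks, an
#' optional best-frequency block, per-unit spike trains (inhomogeneous
#' Poisson, thinned against the closed-form rate profile), and per-site LFP
#' traces. Fully deterministic given `config$seed`; every unit x trial and
#' site x trial uses its own derived substream.
#'
#' @param config a [session_config].
#' @return object of class `ephys_session`: list with `events`
#'   (data.frame), `spikes` (data.frame: `unit_id`, `trial_id`, `time`),
#'   `lfp` (per-site list: `data` trials x samples matrix, `trial_ids`,
#'   `sampling_rate`, `t0`), `units` (per-unit parameter table), `sites`,
#'   `schedules`, `config`.
#' @export
generate_session <- function(config = session_config()) {
  stopifnot(inherits(config, "session_config"))
  tasks <- c("TASK1", "TASK2")
  sched <- lapply(tasks, sequence_schedule, go_fraction = config$go_fraction)
  names(sched) <- tasks
  tone_p <- lapply(sched, tone_probabilities)

  events <- with_substream(substream_seed(config$seed, 1), {
    rows <- list()
    trial_id <- 0L
    block_id <- 0L
    t_s1 <- config$s1_onset
    t_s2 <- t_s1 + config$stimulus_onset_interval
    dur <- config$tone_duration
    t_end <- t_s2 + dur + config$response_window[2] + 0.25
    start_task <- sample(tasks, 1)
    task_order <- rep(if (start_task == "TASK1") tasks else rev(tasks),
                      config$n_blocks_per_task)

    make_block <- function(label, matched_task, phase, n) {
      block_id <<- block_id + 1L
      gf <- config$go_fraction
      if (phase == "task" && config$go_fraction_jitter > 0) {
        gf <- min(0.77, max(0.50, gf + runif(1, -1, 1) * config$go_fraction_jitter))
      }
      s <- sequence_schedule(matched_task, gf)
      seq_ids <- block_sequences(s, n, if (matched_task == "TASK1") "3-3" else "1-1")
      idx <- match(seq_ids, SEQUENCES$seq_id)
      s1f <- SEQUENCES$s1_freq[idx]
      s2f <- SEQUENCES$s2_freq[idx]
      p <- tone_probabilities(sched[[matched_task]])
      df <- data.frame(
        trial_id = trial_id + seq_len(n), block_id = block_id,
        phase = phase, task = label, matched_task = matched_task,
        seq_id = seq_ids, s1_freq = s1f, s2_freq = s2f,
        t_led = 0.2, t_grasp = 0.5, t_s1 = t_s1, t_s2 = t_s2,
        tone_duration = dur, t_end = t_end,
        p_s1 = unname(p[as.character(s1f)]),
        p_s2 = unname(p[as.character(s2f)]),
        iti = NA_real_, required = NA_character_,
        t_release = NA_real_, outcome = NA_character_,
        stringsAsFactors = FALSE)
      trial_id <<- trial_id + n
      if (phase == "task") {
        df$required <- required_response(label, df$s1_freq, df$s2_freq)
        lab1 <- label_condition(label, "S1", df$s1_freq)
        fa_rate <- ifelse(lab1 == "S1_NO_GO",
                          config$fa_rate_s1nogo, config$fa_rate_s2nogo)
        u <- runif(n)
        released <- ifelse(df$required == "GO",
                           u >= config$miss_rate, u < fa_rate)
        rel <- runif(n, 0.15, min(1.0, config$response_window[2] - 0.05))
        df$t_release <- ifelse(released, t_s2 + dur + rel, NA_real_)
        df$outcome <- classify_outcome(
          df$required,
          ifelse(released, rel, NA_real_),
          config$response_window)
      } else if (phase == "passive") {
        df$iti <- runif(n, 3.5, 4.5)
      }
      df
    }

    for (tk in task_order) rows[[length(rows) + 1L]] <-
      make_block(tk, tk, "task", config$trials_per_block)
    if (config$include_passive) {
      rows[[length(rows) + 1L]] <-
        make_block("PASSIVE1", "TASK1", "passive", config$trials_per_block)
      rows[[length(rows) + 1L]] <-
        make_block("PASSIVE2", "TASK2", "passive", config$trials_per_block)
    }
    if (config$include_bf_block) {
      block_id <- block_id + 1L
      freqs <- 2^seq(log2(62.5), log2(16000), length.out = 40)
      order <- sample(rep(seq_len(40), 10))
      n <- length(order)
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = trial_id + seq_len(n), block_id = block_id,
        phase = "bf", task = "BF", matched_task = NA_character_,
        seq_id = NA_character_, s1_freq = freqs[order], s2_freq = NA_real_,
        t_led = NA_real_, t_grasp = NA_real_, t_s1 = 0.2, t_s2 = NA_real_,
        tone_duration = 0.1, t_end = 0.5,
        p_s1 = 1 / 40, p_s2 = NA_real_, iti = NA_real_,
        required = NA_character_, t_release = NA_real_,
        outcome = NA_character_, stringsAsFactors = FALSE)
      trial_id <- trial_id + n
    }
    do.call(rbind, rows)
  })

  units <- with_substream(substream_seed(config$seed, 2), {
    u0 <- config$unit
    data.frame(
      unit_id = seq_len(config$n_units),
      baseline_rate = rlnorm_vec(config$n_units, u0$baseline_rate,
                                 config$baseline_sdlog),
      best_frequency = exp(runif(config$n_units,
                                 log(config$bf_range[1]),
                                 log(config$bf_range[2]))),
      tuning_bandwidth = u0$tuning_bandwidth,
      evoked_gain = u0$evoked_gain,
      nogo_gain = rlnorm_vec(config$n_units, u0$nogo_gain,
                             config$nogo_gain_sdlog),
      cue_offset_task1 = u0$cue_offset[["TASK1"]],
      cue_offset_task2 = u0$cue_offset[["TASK2"]],
      adaptation_strength = u0$adaptation_strength,
      forward_suppression = u0$forward_suppression,
      motor_ramp_amp = u0$motor_ramp_amp,
      trial_gain_sd = u0$trial_gain_sd,
      nogo_onset = u0$nogo_onset,
      ramp_onset = u0$ramp_onset,
      ramp_peak = u0$ramp_peak)
  })

  spikes <- simulate_session_spikes(events, units, config)

  lfp <- NULL
  sites <- NULL
  if (config$n_lfp_sites > 0) {
    gen <- simulate_session_lfp(events, config)
    lfp <- gen$lfp
    sites <- gen$sites
  }

  structure(
    list(events = events, spikes = spikes, lfp = lfp, units = units,
         sites = sites,
         schedules = data.frame(task = names(tone_p),
                                p_1000 = vapply(tone_p, `[[`, 0, "1000"),
                                p_3000 = vapply(tone_p, `[[`, 0, "3000"),
                                row.names = NULL),
         config = config),
    class = "ephys_session"
  )
}

rlnorm_vec <- function(n, mean, sdlog) {
  if (sdlog <= 0) return(rep(mean, n))
  mean * exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

unit_params_from_row <- function(row) {
  unit_params(
    baseline_rate = row$baseline_rate,
    best_frequency = row$best_frequency,
    tuning_bandwidth = row$tuning_bandwidth,
    evoked_gain = row$evoked_gain,
    nogo_gain = row$nogo_gain,
    cue_offset = c(TASK1 = row$cue_offset_task1, TASK2 = row$cue_offset_task2),
    adaptation_strength = row$adaptation_strength,
    forward_suppression = row$forward_suppression,
    motor_ramp_amp = row$motor_ramp_amp,
    trial_gain_sd = row$trial_gain_sd,
    nogo_onset = row$nogo_onset,
    ramp_onset = row$ramp_onset,
    ramp_peak = row$ramp_peak)
}

simulate_session_spikes <- function(events, units, config) {
  out <- vector("list", nrow(units) * nrow(events))
  k <- 0L
  trials <- split(events, seq_len(nrow(events)))
  for (i in seq_len(nrow(units))) {
    unit <- unit_params_from_row(units[i, ])
    for (tr in trials) {
      k <- k + 1L
      trial <- as.list(tr)
      times <- with_substream(
        substream_seed(config$seed, 100L + i, trial$trial_id), {
          g <- if (unit$trial_gain_sd > 0) {
            exp(rnorm(1, -unit$trial_gain_sd^2 / 2, unit$trial_gain_sd))
          } else 1
          simulate_spike_train(build_rate_profile(unit, trial, gain = g))
        })
      if (length(times)) {
        out[[k]] <- data.frame(unit_id = units$unit_id[i],
                               trial_id = trial$trial_id, time = times)
      }
    }
  }
  res <- data.table::rbindlist(out[!vapply(out, is.null, TRUE)])
  as.data.frame(res)
}

simulate_session_lfp <- function(events, config) {
  ev <- events[events$phase %in% c("task", "passive"), , drop = FALSE]
  p0 <- config$lfp
  fs <- p0$sampling_rate
  dur <- 2.7
  n_samp <- round(dur * fs)
  sites <- with_substream(substream_seed(config$seed, 3), {
    data.frame(site_id = seq_len(config$n_lfp_sites),
               amp_scale = exp(rnorm(config$n_lfp_sites, 0, 0.2)))
  })
  lfp <- vector("list", config$n_lfp_sites)
  for (s in seq_len(config$n_lfp_sites)) {
    params <- p0
    params$amplitude <- p0$amplitude * sites$amp_scale[s]
    mat <- matrix(0, nrow(ev), n_samp)
    t0 <- ev$t_s1[1] - 0.6
    for (j in seq_len(nrow(ev))) {
      trial <- as.list(ev[j, ])
      mat[j, ] <- with_substream(
        substream_seed(config$seed, 200L + s, trial$trial_id),
        simulate_lfp(params, trial, t0 = trial$t_s1 - 0.6,
                     duration = dur)$samples)
    }
    lfp[[s]] <- list(site_id = s, data = mat, trial_ids = ev$trial_id,
                     sampling_rate = fs, t0 = t0)
  }
  list(lfp = lfp, sites = sites)
}

#' @export
print.ephys_session <- function(x, ...) {
  cat(sprintf(
    "<ephys_session> %d trials (%d task, %d passive, %d tuning), %d units, %d LFP sites\n",
    nrow(x$events), sum(x$events$phase == "task"),
    sum(x$events$phase == "passive"), sum(x$events$phase == "bf"),
    nrow(x$units), if (is.null(x$lfp)) 0L else length(x$lfp)))
  invisible(x)
}
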