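# Shared synthetic sessions, generated once per test run.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .session_cache, inherits = FALSE)) {
    assign(key, maker(), envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

# Small session with spikes + LFP, passive blocks, no tuning block.
small_session <- function() {
  cached("small", function() {
    generate_session(session_config(
      n_units = 5, n_lfp_sites = 2, trials_per_block = 80,
      n_blocks_per_task = 1, include_bf_block = FALSE, seed = 42))
  })
}

# Minimal spikes-only session for IO round trips.
mini_session <- function() {
  cached("mini", function() {
    generate_session(session_config(
      n_units = 2, n_lfp_sites = 1, trials_per_block = 40,
      n_blocks_per_task = 1, include_passive = FALSE,
      include_bf_block = FALSE, seed = 11))
  })
}

# A single simulated trial descriptor for profile-level tests.
toy_trial <- function(task = "TASK1", phase = "task", s1_freq = 3000,
                      s2_freq = 1000, outcome = "CORRECT_REJECTION",
                      t_release = NA_real_, p_s1 = 0.5, p_s2 = 0.5) {
  list(phase = phase, task = task, s1_freq = s1_freq, s2_freq = s2_freq,
       t_s1 = 1.0, t_s2 = 2.0, tone_duration = 0.2, t_release = t_release,
       outcome = outcome, p_s1 = p_s1, p_s2 = p_s2, t_end = 3.6)
}

# Simulate per-trial during-window rates for a two-condition comparison
# through the generator machinery (short trials holding only S1).
simulate_condition_rates <- function(unit, n_trials, task, s1_freq = 3000,
                                     p_s1 = 0.5) {
  trial <- list(phase = "task", task = task, s1_freq = s1_freq,
                s2_freq = NA_real_, t_s1 = 0.3, t_s2 = NA_real_,
                tone_duration = 0.2, t_release = NA_real_,
                outcome = "CORRECT_REJECTION", p_s1 = p_s1, p_s2 = NA_real_,
                t_end = 0.6)
  prof <- build_rate_profile(unit, trial)
  vapply(seq_len(n_trials), function(i) {
    mean_rate(simulate_spike_train(prof), c(0.3, 0.55))
  }, 0)
}
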