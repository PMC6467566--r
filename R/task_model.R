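#' Task specification for the two-tone go/no-go paradigm
#'
#' Each task requires the go response (bar release) for exactly one of the
#' four two-tone sequences: 3-3 in Task 1 and 1-1 in Task 2; every other
#' sequence requires the no-go response (continued holding). A coloured LED
#' on one side cues which task is in force.
#'
#' @param task_id `"TASK1"` or `"TASK2"`.
#' @param response_window numeric length-2, seconds after S2 offset within
#'   which a bar release counts as a go response. Half-open `[min, max)`.
#'   The default `c(0.04, 1.16)` is one subject's window; `c(0.04, 1.76)`
#'   is the other's.
#' @param cue free-form descriptor of the visual cue (side, colour).
#' @return an object of class `task_spec`.
#' @examples
#' task_spec("TASK2")
#' @export
task_spec <- function(task_id = c("TASK1", "TASK2"),
                      response_window = c(0.04, 1.16),
                      cue = NULL) {
  task_id <- match.arg(task_id)
  if (length(response_window) != 2 ||
      !(0 < response_window[1] && response_window[1] < response_window[2])) {
    stop_invalid("response_window must satisfy 0 < t_min < t_max")
  }
  go_freq <- if (task_id == "TASK1") 3000 else 1000
  if (is.null(cue)) {
    cue <- if (task_id == "TASK1") "green LED, right" else "red LED, left"
  }
  structure(
    list(task_id = task_id,
         go_sequence = c(go_freq, go_freq),
         go_freq = go_freq,
         response_window = as.numeric(response_window),
         cue = cue),
    class = "task_spec"
  )
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("<task_spec> %s: go for %g-%g Hz; response window [%g, %g) s after S2 offset; cue: %s\n",
              x$task_id, x$go_sequence[1], x$go_sequence[2],
              x$response_window[1], x$response_window[2], x$cue))
  invisible(x)
}

#' Two-tone sequence timing
#'
#' @param s1_freq,s2_freq tone frequencies in Hz, each 1000 or 3000.
#' @param s1_onset trial-relative S1 onset in seconds (anchor supplied by
#'   the events table).
#' @param tone_duration tone duration in seconds (default 0.2).
#' @param stimulus_onset_interval S1-to-S2 onset interval in seconds
#'   (default 1.0, i.e. an 0.8 s gap between S1 offset and S2 onset).
#' @return an object of class `tone_sequence`.
#' @export
tone_sequence <- function(s1_freq, s2_freq, s1_onset = 1.0,
                          tone_duration = 0.2,
                          stimulus_onset_interval = 1.0) {
  check_freq(c(s1_freq, s2_freq))
  if (any(c(s1_onset, tone_duration, stimulus_onset_interval) <= 0)) {
    stop_invalid("all timing fields must be > 0")
  }
  structure(
    list(s1_freq = s1_freq, s2_freq = s2_freq, s1_onset = s1_onset,
         tone_duration = tone_duration,
         stimulus_onset_interval = stimulus_onset_interval,
         s2_onset = s1_onset + stimulus_onset_interval),
    class = "tone_sequence"
  )
}

check_freq <- function(f) {
  if (!all(f %in% c(1000, 3000))) {
    stop_invalid("tone frequencies must be 1000 or 3000 Hz, got: %s",
                 paste(unique(f[!f %in% c(1000, 3000)]), collapse = ", "))
  }
  invisible(f)
}

#' Required motor response for a sequence under a task
#'
#' `"GO"` iff the sequence equals the task's go sequence (3-3 in Task 1,
#' 1-1 in Task 2), otherwise `"NO_GO"`. Vectorised over frequencies.
#'
#' @param task a [task_spec] or `"TASK1"`/`"TASK2"`.
#' @param s1_freq,s2_freq tone frequencies (Hz).
#' @return character vector of `"GO"`/`"NO_GO"`.
#' @examples
#' required_response("TASK1", 3000, 3000)  # "GO"
#' required_response("TASK2", 3000, 3000)  # "NO_GO"
#' @export
required_response <- function(task, s1_freq, s2_freq) {
  task <- as_task_spec(task)
  check_freq(c(s1_freq, s2_freq))
  ifelse(s1_freq == task$go_freq & s2_freq == task$go_freq, "GO", "NO_GO")
}

as_task_spec <- function(task) {
  if (inherits(task, "task_spec")) task else task_spec(task)
}

#' Condition labels
#'
#' The five sensorimotor-association labels a tone presentation can carry.
#' @export
CONDITION_LABELS <- c("S1_NO_GO", "S1_UNCERTAIN", "S2_GO", "S2_NO_GO", "S2_NIL")

#' Sensorimotor-association label of a tone presentation
#'
#' From an ideal observer's standpoint: an S1 at the task's go frequency
#' leaves the required response uncertain (`S1_UNCERTAIN`); an S1 at the
#' other frequency already signals the no-go response (`S1_NO_GO`) and
#' makes S2 uninformative (`S2_NIL`). After an uncertain S1, S2 signals go
#' (`S2_GO`) at the go frequency and no-go (`S2_NO_GO`) at the other.
#' Vectorised over the frequency arguments.
#'
#' @param task a [task_spec] or task id.
#' @param position `"S1"` or `"S2"`.
#' @param tone_freq frequency of the labelled tone (Hz).
#' @param s1_freq frequency of the first tone; required when
#'   `position == "S2"`.
#' @return character vector of labels from [CONDITION_LABELS].
#' @examples
#' label_condition("TASK2", "S1", 3000)          # "S1_NO_GO"
#' label_condition("TASK1", "S2", 3000, 1000)    # "S2_NIL"
#' label_condition("TASK1", "S2", 3000, 3000)    # "S2_GO"
#' @export
label_condition <- function(task, position, tone_freq, s1_freq = NULL) {
  task <- as_task_spec(task)
  position <- match.arg(position, c("S1", "S2"))
  check_freq(tone_freq)
  g <- task$go_freq
  if (position == "S1") {
    return(ifelse(tone_freq == g, "S1_UNCERTAIN", "S1_NO_GO"))
  }
  if (is.null(s1_freq)) {
    stop_invalid("s1_freq must be given to label an S2 presentation")
  }
  check_freq(s1_freq)
  ifelse(s1_freq != g, "S2_NIL",
         ifelse(tone_freq == g, "S2_GO", "S2_NO_GO"))
}

#' Classify the behavioural outcome of a trial
#'
#' A release inside the half-open response window is a go response: a hit
#' when go was required, a false alarm otherwise. No release inside the
#' window is a no-go response: a miss when go was required, a correct
#' rejection otherwise. An absent release (`NA`) is a valid state.
#'
#' @param required `"GO"` or `"NO_GO"` (vectorised).
#' @param release_time seconds after S2 offset, or `NA` for no release.
#' @param window response window, seconds after S2 offset, `[min, max)`.
#' @return character vector: `"HIT"`, `"MISS"`, `"FALSE_ALARM"`, or
#'   `"CORRECT_REJECTION"`.
#' @examples
#' classify_outcome("GO", 0.5, c(0.04, 1.16))     # "HIT"
#' classify_outcome("NO_GO", 0.5, c(0.04, 1.16))  # "FALSE_ALARM"
#' @export
classify_outcome <- function(required, release_time, window = c(0.04, 1.16)) {
  if (!all(required %in% c("GO", "NO_GO"))) {
    stop_invalid("required must be GO or NO_GO")
  }
  released <- !is.na(release_time) &
    release_time >= window[1] & release_time < window[2]
  ifelse(required == "GO",
         ifelse(released, "HIT", "MISS"),
         ifelse(released, "FALSE_ALARM", "CORRECT_REJECTION"))
}

#' Behavioural discriminability (d-prime)
#'
#' `d' = z(hit rate) - z(false-alarm rate)` with `z` the standard-normal
#' quantile. Rates of exactly 0 or 1 are replaced by `1/(2n)` and
#' `1 - 1/(2n)` respectively (n = trial count on that side), so d' stays
#' finite.
#'
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @param n_go,n_nogo trial counts behind the rates (must be >= 1).
#' @return numeric d-prime.
#' @examples
#' dprime(0.9, 0.1, 100, 100)  # 2 * qnorm(0.9)
#' @export
dprime <- function(hit_rate, fa_rate, n_go, n_nogo) {
  if (any(n_go < 1) || any(n_nogo < 1)) {
    stop_invalid("trial counts must be >= 1")
  }
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1)) {
    stop_invalid("rates must lie in [0, 1]")
  }
  h <- correct_extreme(hit_rate, n_go)
  f <- correct_extreme(fa_rate, n_nogo)
  qnorm(h) - qnorm(f)
}

correct_extreme <- function(r, n) {
  r <- ifelse(r <= 0, 1 / (2 * n), r)
  ifelse(r >= 1, 1 - 1 / (2 * n), r)
}

#' Per-task behavioural summary of a session events table
#'
#' Computes, for each task block label, the hit rate on the go sequence and,
#' for each of the three no-go sequences, the false-alarm rate and the
#' d-prime between the go sequence and that no-go sequence.
#'
#' @param events a session events `data.frame` with columns `task`,
#'   `s1_freq`, `s2_freq`, `required`, `outcome` (task-phase rows only are
#'   used).
#' @return a `data.frame`, one row per task x no-go sequence, with columns
#'   `task`, `s1_freq`, `s2_freq`, `n_go`, `n_nogo`, `hit_rate`, `fa_rate`,
#'   `dprime`.
#' @export
behavioral_summary <- function(events) {
  ev <- as.data.frame(events)
  ev <- ev[ev$task %in% c("TASK1", "TASK2"), , drop = FALSE]
  if (nrow(ev) == 0) stop_invalid("no task trials in events table")
  out <- list()
  for (tk in unique(ev$task)) {
    sub <- ev[ev$task == tk, ]
    go <- sub[sub$required == "GO", ]
    n_go <- nrow(go)
    hit_rate <- if (n_go > 0) mean(go$outcome == "HIT") else NA_real_
    nogo <- sub[sub$required == "NO_GO", ]
    seqs <- unique(nogo[, c("s1_freq", "s2_freq")])
    for (i in seq_len(nrow(seqs))) {
      sel <- nogo$s1_freq == seqs$s1_freq[i] & nogo$s2_freq == seqs$s2_freq[i]
      n_ng <- sum(sel)
      fa <- mean(nogo$outcome[sel] == "FALSE_ALARM")
      dp <- if (n_go > 0 && n_ng > 0) dprime(hit_rate, fa, n_go, n_ng) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        task = tk, s1_freq = seqs$s1_freq[i], s2_freq = seqs$s2_freq[i],
        n_go = n_go, n_nogo = n_ng, hit_rate = hit_rate, fa_rate = fa,
        dprime = dp)
    }
  }
  do.call(rbind, out)
}
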