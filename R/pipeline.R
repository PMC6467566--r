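#' Tidy per-unit condition-ratio table for a session
#'
#' Runs responsiveness preselection and then the during/before condition
#' ratios (S1-no-go vs S1-uncertain; S2-no-go vs S2-go) for every
#' responsive unit, frequency, phase and window, and returns one row per
#' combination. Responsiveness is assessed separately per phase, as is the
#' convention for this preselection.
#'
#' @param session an `ephys_session`.
#' @param freqs tone frequencies to analyse.
#' @param positions `"S1"`, `"S2"` or both.
#' @param phases `"task"`, `"passive"` or both (passive skipped when the
#'   session has no passive blocks).
#' @param windows `"during"`, `"before"` or both.
#' @param alpha,n_perm,eps,min_trials analysis parameters.
#' @param responsive_only drop units failing the responsiveness
#'   preselection for that frequency and phase.
#' @return data.frame, one row per unit x freq x position x phase x window.
#' @export
session_spike_ratios <- function(session, freqs = c(3000, 1000),
                                 positions = c("S1", "S2"),
                                 phases = c("task", "passive"),
                                 windows = c("during", "before"),
                                 alpha = 0.05, n_perm = 1000, eps = 0.1,
                                 min_trials = 5, responsive_only = TRUE) {
  if (!any(session$events$phase == "passive")) {
    phases <- setdiff(phases, "passive")
  }
  rows <- list()
  for (phase in phases) {
    for (freq in freqs) {
      for (u in session$units$unit_id) {
        if (responsive_only &&
            !is_responsive(session, u, freq, phase, alpha, n_perm,
                           min_trials)) next
        for (pos in positions) {
          for (win in windows) {
            r <- spike_condition_ratio(session, u, freq, pos, phase, win,
                                       alpha, n_perm, eps, min_trials)
            if (!is.null(r)) rows[[length(rows) + 1L]] <- r
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(unit_id = integer(0), freq = numeric(0),
                      position = character(0), phase = character(0),
                      window = character(0), n_num = integer(0),
                      n_den = integer(0), ratio = numeric(0),
                      p_value = numeric(0), significant = logical(0)))
  }
  do.call(rbind, rows)
}

#' Tidy per-site LFP ratio table for a session
#'
#' LFP mirror of [session_spike_ratios] (500-ms RMS windows).
#'
#' @inheritParams session_spike_ratios
#' @return data.frame, one row per site x freq x position x phase x window.
#' @export
session_lfp_ratios <- function(session, freqs = c(3000, 1000),
                               positions = c("S1", "S2"),
                               phases = c("task", "passive"),
                               windows = c("during", "before"),
                               alpha = 0.05, n_perm = 1000, min_trials = 5,
                               responsive_only = TRUE) {
  if (is.null(session$lfp)) stop_invalid("session has no LFP data")
  if (!any(session$events$phase == "passive")) {
    phases <- setdiff(phases, "passive")
  }
  rows <- list()
  for (phase in phases) {
    for (freq in freqs) {
      for (s in seq_along(session$lfp)) {
        if (responsive_only &&
            !is_responsive_lfp(session, s, freq, phase, alpha, n_perm,
                               min_trials)) next
        for (pos in positions) {
          for (win in windows) {
            r <- site_lfp_ratio(session, s, freq, pos, phase, win, alpha,
                                n_perm, min_trials)
            if (!is.null(r)) rows[[length(rows) + 1L]] <- r
          }
        }
      }
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

# Attribution inputs from a tidy ratio table, for one freq x position.
# Cue attribution: significant before ratios among during-significant
# records; context attribution: passive-significant fraction of the
# during-significant records that were also measurable passively.
attribution_from_table <- function(tab, freq, position) {
  sel <- tab$freq == freq & tab$position == position
  task_during <- tab[sel & tab$phase == "task" & tab$window == "during", ]
  task_before <- tab[sel & tab$phase == "task" & tab$window == "before", ]
  pass_during <- tab[sel & tab$phase == "passive" & tab$window == "during", ]
  n_total <- nrow(task_during)
  if (n_total == 0) return(NULL)
  sig <- task_during[task_during$significant, ]
  before_sig_units <-
    task_before$unit_id[task_before$significant]
  n_cue <- sum(sig$unit_id %in% before_sig_units)
  tested <- sig$unit_id[sig$unit_id %in% pass_during$unit_id]
  n_passive_tested <- length(tested)
  n_passive_sig <- sum(pass_during$significant[
    pass_during$unit_id %in% tested])
  attribution_accounting(
    n_total, nrow(sig), n_cue,
    if (n_passive_tested > 0) n_passive_tested else NA_integer_,
    if (n_passive_tested > 0) n_passive_sig else NA_integer_)
}

# Normalized responses of given units to the six conditions of one tone.
six_condition_responses <- function(session, unit_ids, freq, eps = 0.1,
                                    min_trials = 5) {
  nogo_task <- if (freq == 3000) "TASK2" else "TASK1"
  uncertain_task <- setdiff(c("TASK1", "TASK2"), nogo_task)
  conds <- list(
    S1_NO_GO = list(label = "S1_NO_GO", task = NULL),
    S1_UNCERTAIN = list(label = "S1_UNCERTAIN", task = NULL),
    S2_GO = list(label = "S2_GO", task = NULL),
    S2_NO_GO = list(label = "S2_NO_GO", task = NULL),
    S2_NIL_AFTER_NOGO_S1 = list(label = "S2_NIL", task = nogo_task),
    S2_NIL_SAME_TASK_AS_GO = list(label = "S2_NIL", task = uncertain_task))
  # S2-nil contexts: in the task where the tone's S1 is no-go, the same
  # tone appears as S2-nil after itself; in the other task it appears as
  # S2-nil after the other frequency. Label columns by task for clarity.
  names(conds)[5:6] <- paste0("S2_NIL_", c(nogo_task, uncertain_task))
  mat <- sapply(conds, function(cn) {
    vapply(unit_ids, function(u) {
      normalized_response(session, u, freq, cn$label, task = cn$task,
                          eps = eps, min_trials = min_trials)
    }, 0)
  })
  mat <- matrix(mat, nrow = length(unit_ids),
                dimnames = list(unit_ids, names(conds)))
  mat
}

# Geometric-mean normalized PSTH traces (and per-bin tests) for a
# condition pair over a set of units.
population_traces <- function(session, unit_ids, freq, position,
                              eps = 0.1, bin_width = 0.010,
                              range = c(-0.05, 1.0), min_units = 6) {
  pair <- if (position == "S1") c("S1_NO_GO", "S1_UNCERTAIN")
          else c("S2_NO_GO", "S2_GO")
  mats <- lapply(pair, function(cond) {
    tr <- condition_trials(session, freq, cond)
    norm <- t(vapply(unit_ids, function(u) {
      h <- unit_psth(session, u, tr, bin_width, range)
      floor_rate(h$rate, eps) / floor_rate(h$baseline, eps)
    }, numeric(round(diff(range) / bin_width))))
    norm
  })
  centers <- seq(range[1], range[2], by = bin_width)
  centers <- centers[-length(centers)] + bin_width / 2
  traces <- lapply(mats, function(m) {
    structure(list(bin_centers = centers, values = exp(colMeans(log(m))),
                   n_units = nrow(m)), class = "normalized_trace")
  })
  names(traces) <- pair
  list(traces = traces,
       p_values = per_bin_condition_test(mats[[1]], mats[[2]], min_units),
       bin_centers = centers)
}

#' Full analysis of one session
#'
#' Runs the pipeline: responsiveness preselection, during/before spike
#' ratios with permutation tests (task and passive), population summaries
#' and confound-attribution accounting per frequency and position, the
#' six-condition comparison over units with significant during ratios,
#' normalized population traces, false-alarm contrasts, and (optionally)
#' the LFP mirror of the ratio analyses.
#'
#' @param session an `ephys_session`.
#' @param freqs tone frequencies to analyse (default both).
#' @param alpha,n_perm,eps,min_trials analysis parameters.
#' @param do_lfp,do_traces,do_fa toggle the LFP branch, the population
#'   traces, and the false-alarm contrasts.
#' @return list of class `session_analysis` with elements `spike_ratios`,
#'   `population`, `attribution`, `six_condition`, `traces`,
#'   `false_alarm`, `lfp_ratios`, `lfp_attribution`, `behavior`, `params`.
#' @export
analyze_session <- function(session, freqs = c(3000, 1000), alpha = 0.05,
                            n_perm = 1000, eps = 0.1, min_trials = 5,
                            do_lfp = !is.null(session$lfp),
                            do_traces = TRUE, do_fa = TRUE) {
  tab <- session_spike_ratios(session, freqs = freqs, alpha = alpha,
                              n_perm = n_perm, eps = eps,
                              min_trials = min_trials)
  message(sprintf("spike ratios: %d records from %d units",
                  nrow(tab), length(unique(tab$unit_id))))
  population <- list()
  attribution <- list()
  six_condition <- list()
  traces <- list()
  for (freq in freqs) {
    for (pos in c("S1", "S2")) {
      key <- sprintf("%g_%s", freq, pos)
      sel <- tab$freq == freq & tab$position == pos &
        tab$phase == "task" & tab$window == "during"
      if (any(sel)) {
        population[[key]] <- summarize_ratios(tab$ratio[sel],
                                              tab$p_value[sel], alpha)
        at <- attribution_from_table(tab, freq, pos)
        if (!is.null(at)) attribution[[key]] <- at
      }
    }
    sig_units <- unique(tab$unit_id[
      tab$freq == freq & tab$phase == "task" & tab$window == "during" &
        tab$significant])
    if (length(sig_units) >= 2) {
      six_condition[[as.character(freq)]] <- six_condition_comparison(
        six_condition_responses(session, sig_units, freq, eps, min_trials),
        alpha)
    }
    if (do_traces) {
      for (pos in c("S1", "S2")) {
        su <- unique(tab$unit_id[
          tab$freq == freq & tab$position == pos & tab$phase == "task" &
            tab$window == "during" & tab$significant])
        if (length(su) >= 1) {
          traces[[sprintf("%g_%s", freq, pos)]] <-
            population_traces(session, su, freq, pos, eps)
        }
      }
    }
  }
  false_alarm <- NULL
  if (do_fa) {
    eligible <- tab[tab$phase == "task" & tab$window == "during" &
                      tab$significant, c("unit_id", "freq", "position")]
    if (nrow(eligible) > 0) {
      false_alarm <- false_alarm_contrast(session, eligible,
                                          min_fa = min_trials, eps = eps,
                                          min_trials = min_trials)
    }
  }
  lfp_ratios <- NULL
  lfp_attribution <- list()
  if (do_lfp) {
    lfp_ratios <- session_lfp_ratios(session, freqs = freqs, alpha = alpha,
                                     n_perm = n_perm,
                                     min_trials = min_trials)
    if (!is.null(lfp_ratios)) {
      ltab <- lfp_ratios
      names(ltab)[names(ltab) == "site_id"] <- "unit_id"
      for (freq in freqs) {
        for (pos in c("S1", "S2")) {
          at <- attribution_from_table(ltab, freq, pos)
          if (!is.null(at)) {
            lfp_attribution[[sprintf("%g_%s", freq, pos)]] <- at
          }
        }
      }
    }
  }
  structure(
    list(spike_ratios = tab, population = population,
         attribution = attribution, six_condition = six_condition,
         traces = traces, false_alarm = false_alarm,
         lfp_ratios = lfp_ratios, lfp_attribution = lfp_attribution,
         behavior = behavioral_summary(session$events),
         params = list(freqs = freqs, alpha = alpha, n_perm = n_perm,
                       eps = eps, min_trials = min_trials)),
    class = "session_analysis")
}

#' Write a machine- and human-readable analysis report
#'
#' Emits `report.json` (population statistics, attribution accounting with
#' an explicit "not estimable" marker when passive data are absent,
#' six-condition matrices, false-alarm contrasts, behaviour) plus tidy
#' CSVs (`spike_ratios.csv`, `lfp_ratios.csv`, `behavior.csv`), logging
#' per-stage counts so every denominator is auditable.
#'
#' @param analysis a [analyze_session] result.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_report <- function(analysis, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(analysis$spike_ratios,
                     file.path(path, "spike_ratios.csv"))
  if (!is.null(analysis$lfp_ratios)) {
    data.table::fwrite(analysis$lfp_ratios,
                       file.path(path, "lfp_ratios.csv"))
  }
  data.table::fwrite(analysis$behavior, file.path(path, "behavior.csv"))
  rep <- report_list(analysis)
  jsonlite::write_json(rep, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("report written to %s (%d spike-ratio records)", path,
                  nrow(analysis$spike_ratios)))
  invisible(path)
}

report_list <- function(analysis) {
  att <- lapply(analysis$attribution, function(a) {
    out <- unclass(a)
    if (!a$context_estimable) out$n_context_attributed <- "not estimable"
    out
  })
  fa <- if (is.null(analysis$false_alarm)) NULL else {
    lapply(unclass(analysis$false_alarm), function(x) {
      list(n = x$n, median = x$median, p_value = x$p_value)
    })
  }
  list(
    population = lapply(analysis$population, unclass),
    attribution = att,
    six_condition = lapply(analysis$six_condition, function(s) {
      list(medians = as.list(s$medians),
           p_matrix = s$p_matrix,
           alpha_corrected = s$alpha_corrected)
    }),
    false_alarm = fa,
    lfp_attribution = lapply(analysis$lfp_attribution, function(a) {
      out <- unclass(a)
      if (!a$context_estimable) out$n_context_attributed <- "not estimable"
      out
    }),
    behavior = analysis$behavior,
    params = analysis$params)
}
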