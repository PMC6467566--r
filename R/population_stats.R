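#' Population summary of condition ratios
#'
#' Median ratio with a two-sided Wilcoxon signed-rank test of `log(ratio)`
#' against 0 (i.e. the median against 1), plus counts of individually
#' significant ratios and of those above 1.
#'
#' @param ratios per-unit ratios (> 0).
#' @param p_values aligned per-unit permutation p-values.
#' @param alpha per-unit significance level.
#' @return list of class `population_ratio_summary`: `n_units`, `median`,
#'   `range`, `p_median`, `n_significant`, `n_significant_gt1`,
#'   `fraction_significant`.
#' @export
summarize_ratios <- function(ratios, p_values, alpha = 0.05) {
  if (length(ratios) == 0) stop_invalid("no ratios to summarize")
  if (length(ratios) != length(p_values)) {
    stop_invalid("ratios and p_values must be aligned")
  }
  lr <- log(ratios)
  p_med <- if (all(lr == 0)) 1 else {
    suppressWarnings(wilcox.test(lr, mu = 0)$p.value)
  }
  sig <- p_values < alpha
  structure(
    list(n_units = length(ratios), median = median(ratios),
         range = range(ratios), p_median = p_med,
         n_significant = sum(sig),
         n_significant_gt1 = sum(sig & ratios > 1),
         fraction_significant = mean(sig)),
    class = "population_ratio_summary")
}

#' @export
print.population_ratio_summary <- function(x, ...) {
  cat(sprintf(
    "ratios: n=%d, median %.2f (range %.2f-%.2f), median-vs-1 p=%.3g; significant %d/%d (%.1f%%), of which >1: %d\n",
    x$n_units, x$median, x$range[1], x$range[2], x$p_median,
    x$n_significant, x$n_units, 100 * x$fraction_significant,
    x$n_significant_gt1))
  invisible(x)
}

#' Compare two proportions (chi-square, optionally one-tailed)
#'
#' A 2x2 chi-square test without continuity correction. For one-tailed
#' alternatives, the p-value is half the two-tailed p when the observed
#' direction matches the alternative, `1 - p/2` otherwise, and 0.5 when the
#' proportions are equal. Fisher's exact test is available for small
#' counts.
#'
#' @param k1,n1 successes and total of the first group.
#' @param k2,n2 successes and total of the second group.
#' @param alternative `"two.sided"`, `"greater"` (p1 > p2) or `"less"`.
#' @param method `"chisq"` or `"fisher"`.
#' @return list with `p_value`, `p1`, `p2`, `method`.
#' @export
compare_proportions <- function(k1, n1, k2, n2,
                                alternative = c("two.sided", "greater",
                                                "less"),
                                method = c("chisq", "fisher")) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  if (n1 == 0 || n2 == 0) stop_invalid("group totals must be > 0")
  if (k1 > n1 || k2 > n2) stop_invalid("successes cannot exceed totals")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  p1 <- k1 / n1
  p2 <- k2 / n2
  if (method == "fisher") {
    alt <- switch(alternative, two.sided = "two.sided",
                  greater = "greater", less = "less")
    p <- fisher.test(tab, alternative = alt)$p.value
    return(list(p_value = p, p1 = p1, p2 = p2, method = method))
  }
  p_two <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  p <- if (alternative == "two.sided") {
    p_two
  } else if (p1 == p2) {
    0.5
  } else {
    match_dir <- (alternative == "greater") == (p1 > p2)
    if (match_dir) p_two / 2 else 1 - p_two / 2
  }
  list(p_value = p, p1 = p1, p2 = p2, method = method)
}

#' Confound-attribution accounting for significant condition ratios
#'
#' Conservative bookkeeping that lower-bounds the fraction of significant
#' during-tone ratios attributable to the sensorimotor association itself:
#' ratios whose before-tone ratio was also significant are attributed to
#' the visual cue; of the significant units also tested passively, the
#' passive-significant fraction is projected onto all significant units
#' (rounded) and attributed to the acoustic context; the remainder is the
#' association-attributed lower bound.
#'
#' @param n_total units tested during task performance.
#' @param n_during_sig units with significant during-tone ratios.
#' @param n_also_before_sig of those, units whose before-tone ratio was
#'   also significant (cue-attributed).
#' @param n_passive_tested of the significant units, how many were also
#'   tested in the passive condition. `NA` or 0 marks context attribution
#'   as not estimable (no passive data).
#' @param n_passive_sig of those, units significant also passively.
#' @return list of class `attribution_result`: the input counts plus
#'   `n_cue_attributed`, `n_context_attributed`, `n_remainder`,
#'   `pct_remainder_of_sig` (1 decimal), `pct_remainder_of_sig_int`
#'   (integer rendering), `pct_remainder_of_total` (1 decimal),
#'   `context_estimable`.
#' @examples
#' attribution_accounting(298, 124, 47, 63, 11)  # remainder 55; 44.4%; 18.5%
#' @export
attribution_accounting <- function(n_total, n_during_sig, n_also_before_sig,
                                   n_passive_tested, n_passive_sig) {
  if (n_also_before_sig > n_during_sig) {
    stop_invalid("cue-attributed count exceeds significant count")
  }
  estimable <- !is.na(n_passive_tested) && n_passive_tested > 0
  if (estimable) {
    if (is.na(n_passive_sig) || n_passive_sig > n_passive_tested ||
        n_passive_tested > n_during_sig) {
      stop_invalid("passive counts inconsistent")
    }
    n_context <- round(n_during_sig * n_passive_sig / n_passive_tested)
  } else {
    n_context <- 0L
  }
  n_remainder <- n_during_sig - n_also_before_sig - n_context
  if (n_remainder < 0) stop_invalid("negative remainder: inconsistent inputs")
  pct_sig <- if (n_during_sig > 0) 100 * n_remainder / n_during_sig
             else NA_real_
  structure(
    list(n_total = n_total, n_during_sig = n_during_sig,
         n_cue_attributed = n_also_before_sig,
         n_passive_tested = if (estimable) n_passive_tested else NA_integer_,
         n_passive_sig = if (estimable) n_passive_sig else NA_integer_,
         n_context_attributed = n_context,
         n_remainder = n_remainder,
         pct_remainder_of_sig = round(pct_sig, 1),
         pct_remainder_of_sig_int = round(pct_sig),
         pct_remainder_of_total = round(100 * n_remainder / n_total, 1),
         context_estimable = estimable),
    class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("attribution: %d/%d significant; cue %d, context %s; remainder %d (%.1f%% of significant, %.1f%% of %d tested)\n",
              x$n_during_sig, x$n_total, x$n_cue_attributed,
              if (x$context_estimable) as.character(x$n_context_attributed)
              else "not estimable",
              x$n_remainder, x$pct_remainder_of_sig,
              x$pct_remainder_of_total, x$n_total))
  invisible(x)
}

#' Six-condition comparison of normalized responses
#'
#' Pairwise two-sided Wilcoxon signed-rank tests of the per-unit normalized
#' responses to the same tone across the six conditions it can occur in
#' (S1-no-go, S1-uncertain, S2-go, S2-no-go, and the two S2-nil contexts),
#' with the per-pair significance threshold `alpha / 4` (each no-go
#' condition is compared against four non-no-go conditions). Unpaired
#' values are dropped pairwise (with a message).
#'
#' @param responses units x conditions matrix (or data.frame) of normalized
#'   responses; column names identify the conditions.
#' @param alpha uncorrected level; the threshold applied is `alpha / 4`.
#' @return list of class `six_condition_result`: `medians`, `p_matrix`,
#'   `n_matrix`, `alpha_corrected`, `significant` (logical matrix).
#' @export
six_condition_comparison <- function(responses, alpha = 0.05) {
  responses <- as.matrix(responses)
  conds <- colnames(responses)
  if (is.null(conds)) stop_invalid("responses must have condition names")
  k <- length(conds)
  p <- matrix(NA_real_, k, k, dimnames = list(conds, conds))
  nmat <- matrix(0L, k, k, dimnames = list(conds, conds))
  dropped <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ok <- stats::complete.cases(responses[, c(i, j)])
      dropped <- dropped + sum(!ok)
      a <- responses[ok, i]
      b <- responses[ok, j]
      nmat[i, j] <- nmat[j, i] <- length(a)
      if (length(a) < 2) next
      p[i, j] <- p[j, i] <- if (all(a == b)) 1 else
        suppressWarnings(wilcox.test(a, b, paired = TRUE,
                                     exact = FALSE)$p.value)
    }
  }
  if (dropped > 0) message(sprintf("%d unpaired values dropped pairwise",
                                   dropped))
  structure(
    list(medians = apply(responses, 2, median, na.rm = TRUE),
         p_matrix = p, n_matrix = nmat, alpha_corrected = alpha / 4,
         significant = p < alpha / 4),
    class = "six_condition_result")
}

#' False-alarm versus correct-trial response contrasts
#'
#' For units with significant during-tone ratios and at least `min_fa`
#' false-alarm trials, computes per unit x frequency the ratio of the
#' baseline-normalized response in false-alarm trials to that in correct
#' trials, for three contrasts: S1-no-go FA / S1-no-go correct, S2-no-go FA
#' / S2-no-go correct, and S2-no-go FA / S2-go correct. Records for the two
#' frequencies are pooled (a unit eligible at both frequencies contributes
#' twice). Each pooled set gets a median and a two-sided signed-rank test
#' of log(ratio) against 0.
#'
#' @param session an `ephys_session` (or list of sessions, pooled).
#' @param eligible data.frame with columns `unit_id`, `freq`, `position`
#'   marking unit x frequency records with significant during ratios (e.g.
#'   the significant rows of [session_spike_ratios] output); for
#'   multi-session input add a `session` column matching
#'   `names(sessions)`.
#' @param min_fa minimum false-alarm trials (default 5).
#' @param eps,min_trials passed to [normalized_response] for the correct
#'   trials.
#' @return list of class `false_alarm_contrast` with one element per
#'   contrast: `records` (data.frame), `median`, `p_value`, `n`.
#' @export
false_alarm_contrast <- function(session, eligible, min_fa = 5, eps = 0.1,
                                 min_trials = 5) {
  sessions <- if (inherits(session, "ephys_session")) list(session)
              else session
  if (is.null(names(sessions))) names(sessions) <- seq_along(sessions)
  if (is.null(eligible$session)) eligible$session <- names(sessions)[1]
  contrasts <- list(
    s1_nogo_fa_vs_correct = list(pos = "S1", fa_label = "S1_NO_GO",
                                 corr_label = "S1_NO_GO"),
    s2_nogo_fa_vs_correct_nogo = list(pos = "S2", fa_label = "S2_NO_GO",
                                      corr_label = "S2_NO_GO"),
    s2_nogo_fa_vs_correct_go = list(pos = "S2", fa_label = "S2_NO_GO",
                                    corr_label = "S2_GO"))
  out <- lapply(names(contrasts), function(cn) {
    spec <- contrasts[[cn]]
    recs <- list()
    el <- eligible[eligible$position == spec$pos, , drop = FALSE]
    for (r in seq_len(nrow(el))) {
      ses <- sessions[[as.character(el$session[r])]]
      uid <- el$unit_id[r]
      fq <- el$freq[r]
      fa_tr <- condition_trials(ses, fq, spec$fa_label,
                                outcomes = "FALSE_ALARM")
      if (nrow(fa_tr) < min_fa) next
      fa_resp <- normalized_response(ses, uid, fq, spec$fa_label,
                                     outcomes = "FALSE_ALARM",
                                     eps = eps, min_trials = min_fa)
      corr_resp <- normalized_response(ses, uid, fq, spec$corr_label,
                                       eps = eps, min_trials = min_trials)
      if (is.na(fa_resp) || is.na(corr_resp)) next
      recs[[length(recs) + 1L]] <- data.frame(
        session = el$session[r], unit_id = uid, freq = fq,
        n_fa = nrow(fa_tr), fa_response = fa_resp,
        correct_response = corr_resp, ratio = fa_resp / corr_resp)
    }
    if (length(recs) == 0) {
      message(sprintf("no eligible unit x frequency records for %s", cn))
      return(list(records = NULL, median = NA_real_, p_value = NA_real_,
                  n = 0L))
    }
    tab <- do.call(rbind, recs)
    lr <- log(tab$ratio)
    p <- if (all(lr == 0)) 1 else
      suppressWarnings(wilcox.test(lr, mu = 0)$p.value)
    list(records = tab, median = median(tab$ratio), p_value = p,
         n = nrow(tab))
  })
  names(out) <- names(contrasts)
  structure(out, class = "false_alarm_contrast")
}

#' Median tone-probability ratio across sessions
#'
#' Per session, the ratio of the probabilities of a tone frequency in the
#' two tasks; the statistic is the median of those ratios.
#'
#' @param p_task1,p_task2 per-session probabilities of the tone in Task 1
#'   and Task 2.
#' @return list with `ratios` and `median_ratio`.
#' @examples
#' probability_ratio_summary(0.73, 0.27)$median_ratio  # 2.70...
#' @export
probability_ratio_summary <- function(p_task1, p_task2) {
  if (length(p_task1) != length(p_task2)) {
    stop_invalid("per-session probability vectors must be aligned")
  }
  r <- p_task1 / p_task2
  list(ratios = r, median_ratio = median(r))
}

#' Tone-probability subset analysis
#'
#' Splits sessions at the median of the per-session probability ratio
#' (Task 1 over Task 2) and compares, between the two subsets, the
#' proportion of unit records with significant during-tone ratios > 1
#' (one-tailed chi-square in the direction predicted by stimulus-specific
#' adaptation: the high-ratio subset should have the larger proportion).
#'
#' @param unit_table data.frame with one row per unit record: columns
#'   `session`, `ratio`, `significant`.
#' @param session_probs data.frame with columns `session`, `p_task1`,
#'   `p_task2`.
#' @return list of class `probability_subset_result`: `median_ratio`,
#'   per-subset counts/proportions, and the one-tailed `p_value`.
#' @export
probability_subset_analysis <- function(unit_table, session_probs) {
  pr <- probability_ratio_summary(session_probs$p_task1,
                                  session_probs$p_task2)
  med <- pr$median_ratio
  high_sessions <- session_probs$session[pr$ratios > med]
  low_sessions <- session_probs$session[pr$ratios <= med]
  if (length(high_sessions) < 2 || length(low_sessions) < 2) {
    stop_invalid("need at least 2 sessions per subset (got %d and %d)",
                 length(high_sessions), length(low_sessions))
  }
  in_high <- unit_table$session %in% high_sessions
  sig_gt1 <- unit_table$significant & unit_table$ratio > 1
  k1 <- sum(sig_gt1[in_high]); n1 <- sum(in_high)
  k2 <- sum(sig_gt1[!in_high]); n2 <- sum(!in_high)
  cmp <- compare_proportions(k1, n1, k2, n2, alternative = "greater")
  structure(
    list(median_ratio = med,
         high = list(k = k1, n = n1, prop = cmp$p1),
         low = list(k = k2, n = n2, prop = cmp$p2),
         p_value = cmp$p_value),
    class = "probability_subset_result")
}
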