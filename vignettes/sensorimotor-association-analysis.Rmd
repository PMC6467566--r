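---
title: "Analysing sensorimotor associations in two-tone go/no-go electrophysiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing sensorimotor associations in two-tone go/no-go electrophysiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audassoc)
```

## The experimental logic

`audassoc` analyses recordings made while a subject performs two go/no-go
tasks on the same four two-tone sequences (tones of 1 and 3 kHz, 200 ms
each, separated by an 800 ms gap). In Task 1 the go response — releasing a
touch bar shortly after the second tone — is required only for the 3–3
sequence; in Task 2 only for 1–1. Because the same physical tone demands
different actions in the two tasks, comparing the neuronal response to a
given tone across tasks probes whether a brain area represents the
*sensorimotor association* of the tone rather than its acoustics.

Each tone presentation carries one of five association labels, computed by
`label_condition()` from the task and the tone's position:

* **S1-no-go** — the first tone already determines that no-go is required
  (it is not the task's go frequency);
* **S1-uncertain** — the first tone is the go frequency, so the required
  response is still open;
* **S2-go** / **S2-no-go** — after an uncertain S1, the second tone
  resolves the trial one way or the other;
* **S2-nil** — after an S1-no-go the second tone is uninformative.

The central statistic is the **during-tone condition ratio**: the
trial-averaged spike rate during a tone when it is (say) S1-no-go, divided
by the trial-averaged rate for the same tone as S1-uncertain, using a
250 ms window from tone onset to 50 ms after offset. A permutation test
(`permutation_test_ratio()`) shuffles trials between the two conditions to
assess each unit's ratio. The LFP mirror uses the RMS of the evoked
potential over 500 ms windows.

Two confounds are accounted for rather than ignored:

1. **Visual cue.** The tasks are cued by different LEDs, which can shift
   tonic firing. Ratios computed in the 250 ms *before* the tone measure
   this; a during-significant unit whose before-ratio is also significant
   is conservatively attributed to the cue.
2. **Acoustic context.** The go fraction (~60%) makes the go tone's
   frequency about 2.7 times more probable in its own task, so
   stimulus-specific adaptation alone could produce ratios above 1.
   Passive blocks replaying the two probability schedules without the task
   estimate this pathway; the passive-significant fraction of the tested
   units is projected (rounded) onto all significant units.

`attribution_accounting()` subtracts both attributions; the remainder is a
lower bound on units carrying association information. A complementary
check splits sessions at the median tone-probability ratio
(`probability_subset_analysis()`): if adaptation were the whole story,
sessions with more extreme probabilities should show more significant
ratios, in a known direction.

## The synthetic-session generator

No recordings are distributed with this problem class, so the package
ships a generator (`generate_session()`) whose defaults encode the study
conditions the analysis expects:

* alternating task blocks of 140 trials, 2 blocks per task by default
  (sessions in this paradigm run 2–8 blocks), go required in 60% of
  trials (admissible 50–77%) under a stratified scheme (exact go count per
  block, the three no-go sequences splitting the rest evenly);
* with the go sequence at probability 0.60 and the other three equal, the
  go tone's frequency has probability 0.733 in its own task and 0.267 in
  the other — the 2.70 probability-ratio structure above;
* false-alarm rates of 0.16 on sequences where S1 signals no-go and 0.05
  where only S2 does; a 5% miss rate; release times uniform inside the
  response window (40–1160 ms after S2 offset by default, the stricter of
  the two subjects' windows; the 40–1760 ms variant is a configuration);
* passive blocks replaying both probability schedules with inter-sequence
  intervals uniform on 3.5–4.5 s, and a tuning block of 40 tones log-spaced
  over 0.0625–16 kHz (10 repetitions, 100 ms tones, 500 ms onset interval).

Spike trains are inhomogeneous Poisson samples (thinning) from a
closed-form rate profile per unit and trial:

* baseline 20 spikes/s, plus a task-specific tonic **cue offset**
  (default +1 spikes/s in Task 2) present throughout the trial;
* a tone-evoked elevation of `baseline × (evoked_gain − 1)` (default gain
  3) scaled by Gaussian log-frequency tuning (SD 1.5 octaves around a
  log-uniform best frequency), by **adaptation** `1 − a·p` with `a = 0.15`
  and `p` the tone's probability in its block, and by **forward
  suppression** (×0.7) when S2 repeats S1's frequency;
* a multiplicative **no-go gain** (default 1.3) applied from 70 ms after
  tone onset — the latency at which population traces in this paradigm
  diverge — to the end of the evoked window. For a 250 ms window this
  yields a window-mean ratio of `(0.07 + 0.18·g)/0.25` (1.216 at
  `g = 1.3`), the closed form the tests check against;
* a triangular **motor ramp** (peak 15 spikes/s, onset 300 ms and peak
  200 ms before the bar release) on every release trial;
* a per-trial lognormal gain (SD 0.25 in log) modelling slow excitability
  fluctuations, which gives per-trial rate variance beyond Poisson — the
  main reason single units are often individually nonsignificant while
  population medians are not, as in real data.

Crucially, the no-go gain is **withheld on false-alarm trials**: the
simulated response follows what the subject did, not what it should have
done. This is the structure the error-trial contrast
(`false_alarm_contrast()`) measures — responses to the no-go tone are
weaker in false alarms than in correct no-go trials, but resemble correct
go responses.

LFP traces are two Gaussian-envelope deflections per tone (the second
scaled by its own no-go gain, default 1.5) over 1/f Gaussian noise
band-limited to 1–140 Hz, the recording bandwidth this paradigm uses.

Every unit × trial and site × trial draws from its own counter-derived
RNG substream, so a bundle is byte-identical under a fixed seed and adding
units never perturbs existing ones.

### What the generator does and does not emulate

The generator reproduces the *statistical* structure the analysis relies
on: condition-dependent gains, cue offsets, probability-driven adaptation,
forward suppression, motor ramps, behavioural error rates, and block
design. It does not model spike waveforms, inter-unit correlations beyond
shared trial structure, biophysical LFP generation, learning within a
session, or attention. Passing tests therefore show that the *pipeline*
measures what it claims to measure on data with known ground truth — not
that real cortex behaves like the generator.

One structural consequence matters for the error-trial analysis: in the
generator all effects are multiplicative, so the S2-no-go versus S2-go
comparison (different stimulus histories) always carries the forward
suppression factor. The check that false-alarm responses to the no-go
tone resemble correct go responses is therefore run on a variant with
forward suppression disabled, isolating the behaviour-coupled component;
with suppression on, that contrast reflects stimulus history (≈1.3) by
construction.

## Statistical choices

* **Windows.** Half-open `[start, end)` everywhere. Spikes: 250 ms during
  (tone onset to offset + 50 ms, including offset responses) and the
  abutting 250 ms before. LFP: 500 ms windows. Traces: 10 ms bins.
* **Permutation tests.** Two-sided statistic `|log ratio|`; labels
  shuffled preserving group sizes; exhaustive enumeration whenever the
  number of distinct assignments is at most `n_perm` (default 1000),
  otherwise the add-one estimator `(1 + #exceedances)/(n_perm + 1)`, which
  never returns 0. Degenerate pooled data give p = 1. Responsiveness
  preselection uses a paired sign-flip test of during vs before rates,
  per condition, separately per phase (task/passive), modality and
  frequency.
* **Flooring.** Rates below 0.1 spikes/s are replaced by 0.1 before any
  log or division, so silent windows cannot produce infinite ratios;
  units silent in both conditions are excluded with an error.
* **Minimum trials.** 5 per condition, matching the five-false-alarm
  inclusion threshold used for the error-trial analysis; correct trials
  only enter all ratio analyses except the false-alarm contrasts.
* **Population tests.** Median-vs-1 via two-sided Wilcoxon signed rank on
  log ratios; proportions via 2×2 chi-square without continuity
  correction, one-tailed p defined as half the two-tailed p in the
  observed direction (0.5 at equality), with Fisher's exact test available
  for small counts. The six-condition comparison uses paired signed-rank
  tests at α/4 (each no-go condition faces four non-no-go conditions).
  Per-bin trace comparisons are uncorrected signed-rank tests, skipped
  below 6 units.
* **Attribution rounding.** The context projection is
  `round(n_sig × passive_sig / passive_tested)`; percentages are reported
  to 1 decimal, with an integer rendering also emitted because both
  conventions occur in published accounts of this accounting.
* **LFP RMS ratios** are computed on the trial-averaged evoked potential
  (averaging first suppresses non-phase-locked noise); the permutation
  test regenerates the averages under shuffled trial assignments, which
  the implementation evaluates through a Gram-matrix identity for speed.
  A per-trial variant sits behind a flag. Note that the RMS of an average
  of n noise trials scales as 1/√n, so before-window ratios between
  conditions with unequal trial counts are biased away from 1; the
  permutation test preserves group sizes and remains calibrated, but the
  ratio point estimates in noise-dominated windows should not be
  over-interpreted.
* **Best frequency** is the tone maximising the baseline-subtracted
  evoked rate in a 150 ms window (100 ms tone + 50 ms margin); units with
  no positive evoked response are flagged untuned.

## Problem sizes used in the test suite

The packaged tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the statistical properties are stable: null
calibration over 1000 simulated units (40 trials per side, 999
permutations); gain recovery over 100 units at 80 trials per condition;
qualitative-pattern sessions of 24 units × 8 blocks; error-trial pooling
over 5 sessions of 12 units (false alarms after S2-no-go are rare at rate
0.05, so — as in the source paradigm, which pooled sessions and tone
frequencies — single sessions often fail the five-trial threshold); subset
controls over 8 sessions spanning go fractions 0.50–0.77, which produces
session probability ratios of roughly 2–5.5. Per-unit example ratios and
population medians of the original recordings are not reproducible from
synthetic data; the suite instead checks calibration, recovery, ordering
and the exact bookkeeping identities.

## Limitations

* The generator's effect sizes are chosen for test power and realism of
  structure, not fitted to any recording; absolute ratios and fractions
  significant depend on them.
* During-S2 measures on release trials are contaminated by the motor ramp
  when the release falls early in the response window; no correction is
  applied, matching the analysed paradigm's acknowledged caveat.
* The attribution accounting is deliberately conservative: it treats every
  cue- or context-consistent unit as fully explained by the confound, so
  the remainder is a lower bound.
* Pooling across blocks of the same task within a session is assumed; the
  bundle format carries block ids, so alternative conventions are
  implementable downstream.
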