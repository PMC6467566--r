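Package: audassoc
Title: Sensorimotor-Association Analysis for Two-Tone Go/No-Go Auditory
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing trial-aligned spiking activity and local
    field potentials recorded while a subject performs two alternating
    go/no-go tasks on the same set of two-tone sequences. Implements the
    five-way sensorimotor-association labelling of tone presentations,
    behavioural outcome classification and d-prime, windowed spike-rate and
    RMS-LFP condition ratios with permutation tests, baseline-normalized
    population traces with geometric-mean averaging, confound-attribution
    accounting (visual cue and acoustic context), false-alarm contrasts, and
    a tone-probability subset analysis. Ships an inhomogeneous-Poisson
    session simulator that emulates the statistical structure such studies
    assume, so every stage of the pipeline is testable without recorded
    data, plus a plain-text session bundle format with readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
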