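#' @import data.table
#' @importFrom stats median qnorm rbinom rnorm rpois runif sd wilcox.test
#'   chisq.test fisher.test fft
#' @importFrom utils combn
NULL

# Floor values at eps before they enter a log or a denominator. Applied to
# window means, never to raw spike counts.
floor_rate <- function(x, eps = 0.1) {
  pmax(x, eps)
}

#' Evaluate an expression under a local RNG substream
#'
#' Saves the caller's RNG state, seeds a substream, evaluates `expr`, and
#' restores the state, so consumers of the global stream are unaffected.
#' Used by the session generator to give every unit x trial its own
#' counter-derived substream: adding units or trials never perturbs the
#' spike trains already generated for others.
#'
#' @param seed integer seed for the substream (kept below 2^31).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_substream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic integer substream id from a master seed and counters.
# Plain modular arithmetic on doubles (exact below 2^53), folded into
# [1, 2^31 - 2].
substream_seed <- function(master, ...) {
  counters <- c(...)
  h <- master %% 2147483647
  for (k in counters) {
    h <- (h * 48271 + k * 16807 + 12345) %% 2147483647
  }
  as.integer(h %% 2147483645) + 1L
}

# Half-open interval membership [a, b)
`%inw%` <- function(x, w) {
  x >= w[1] & x < w[2]
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
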