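# Independent brute-force oracles used to freeze expected values.

# Exhaustive permutation p for the between-condition rate-ratio test,
# recomputed from first principles (no package helpers).
oracle_ratio_perm_p <- function(a, b, eps = 0.1) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  stat <- function(x, y) {
    abs(log(max(mean(x), eps) / max(mean(y), eps)))
  }
  obs <- stat(a, b)
  assignments <- utils::combn(n, na)
  stats <- apply(assignments, 2, function(idx) {
    stat(pooled[idx], pooled[-idx])
  })
  mean(stats >= obs - 1e-12)
}

# Exhaustive two-sided sign-flip p for the paired test.
oracle_signflip_p <- function(x, y) {
  d <- x - y
  n <- length(d)
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats <- abs(signs %*% d) / n
  mean(stats >= obs - 1e-12)
}

# Exact two-sided Wilcoxon signed-rank p by sign enumeration (no ties or
# zeros assumed), as an independent check of the median-vs-1 test.
oracle_signed_rank_p <- function(x) {
  r <- rank(abs(x))
  v_obs <- sum(r[x > 0])
  n <- length(x)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p <- 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs))
  min(p, 1)
}

# Log-domain brute-force geometric mean of baseline-normalized traces.
oracle_geo_trace <- function(psths, baselines, eps = 0.1) {
  out <- numeric(ncol(psths))
  for (j in seq_len(ncol(psths))) {
    acc <- 0
    for (i in seq_len(nrow(psths))) {
      acc <- acc + log(max(psths[i, j], eps) / max(baselines[i], eps))
    }
    out[j] <- exp(acc / nrow(psths))
  }
  out
}

# Per-sample RMS oracle.
oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}
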