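# Independent brute-force oracles used to check the fast implementations.
# These deliberately share no code with the package internals.

# exhaustive one-sided randomization p over all baseline/intervention
# label assignments (feasible up to ~10 points)
exhaustive_label_p <- function(baseline, intervention,
                               direction = "decrease_is_effect") {
  pooled <- c(baseline, intervention)
  n <- length(pooled)
  na <- length(baseline)
  sgn <- if (direction == "decrease_is_effect") 1 else -1
  d_of <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    diff <- sgn * (mean(a) - mean(b))
    if (sp > 0) diff / sp else if (diff == 0) 0 else sign(diff) * Inf
  }
  d_obs <- d_of(baseline, intervention)
  splits <- utils::combn(n, na)
  d_all <- apply(splits, 2, function(i) d_of(pooled[i], pooled[-i]))
  list(p = mean(d_all >= d_obs), d_obs = d_obs, n_splits = ncol(splits))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
# (midranks for tied |differences|, zeros dropped by the caller)
enumerate_signed_rank_p <- function(pre, post) {
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1, function(s) sum(r[s]))
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# simple direct Cohen's d (pooled, n-1 weights), no direction handling
plain_pooled_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  (mean(a) - mean(b)) / sp
}
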