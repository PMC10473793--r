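# Independent reference implementations used only to cross-check the
# package; deliberately naive and kept out of R/.

# direct double-loop sample entropy (Richman-Moorman, Chebyshev)
naive_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(A / B)
}

# partial correlation via the inverse covariance (precision) matrix
precision_partial_corr <- function(x, y, covmat) {
  M <- cbind(x = x, y = y, covmat)
  Om <- solve(stats::cov(M))
  -Om["x", "y"] / sqrt(Om["x", "x"] * Om["y", "y"])
}

# literal step-up definition: reject i iff p_i <= the largest threshold
# p_(k) passing p_(k) <= k q / m
naive_bh <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  if (k == 0) rep(FALSE, m) else p <= ps[k]
}

# small, fast synthetic cohort for pipeline-level tests
tiny_cohort <- function(seed = 1, n_case = 10, n_control = 12,
                        n_timepoints = 120, ...) {
  simulate_cohort(simulation_config(n_case = n_case, n_control = n_control,
                                    n_timepoints = n_timepoints, ...),
                  seed = seed)
}
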