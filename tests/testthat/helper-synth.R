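# Shared fixtures, built in code at test time.

# default 6-run design set, TR 2 s, 127 volumes
fixture_designs <- function(n_runs = 6) make_task_design(n_runs = n_runs)

# a pair of condition HRFs inside the span of a known basis, so recovery is
# exact in the noiseless limit; the default grid point is well identified
# under the search grid
fixture_span_hrfs <- function(alpha = 1, tau = 2, L = 2, M = 12, dt = 2) {
  basis <- build_basis(L, M, alpha, tau, 1, dt)
  list(basis = basis, alpha = alpha, tau = tau,
       h_nov = drop(basis$B %*% c(1, 0.5)),
       h_rep = drop(basis$B %*% c(0.6, 0.3)))
}

# ROI series sets: signal + white noise at a chosen signal-to-noise ratio
# (noise SD = signal SD / snr)
fixture_roi_series <- function(designs, h_nov, h_rep, snr = 1, seed = 1) {
  with_seed2(seed, lapply(designs, function(d) {
    s <- conv_causal2(d$x1, h_nov) + conv_causal2(d$x2, h_rep)
    s + stats::rnorm(length(s), sd = stats::sd(s) / snr)
  }))
}

# independent causal convolution oracle: direct O(N*M) double loop
conv_causal2 <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    for (m in seq_along(k)) {
      j <- t - m + 1
      if (j >= 1) out[t] <- out[t] + k[m] * x[j]
    }
  }
  out
}

# seed scoping without touching the package internals
with_seed2 <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
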