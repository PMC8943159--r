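#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state afterwards.
# All generators route their randomness through this so that identical seeds
# give bit-identical outputs without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a master seed; keeps values inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483647L)
}

# Causal discrete convolution of a signal with a finite kernel, truncated to
# the signal length: out[n] = sum_k kernel[k+1] * x[n-k].
conv_causal <- function(x, kernel) {
  drop(lag_matrix(x, length(kernel)) %*% kernel)
}

# n x nk matrix whose row t is (x[t], x[t-1], ..., x[t-nk+1]) with zeros
# before the series start; lag_matrix(x, nk) %*% k is the causal convolution.
lag_matrix <- function(x, nk) {
  stats::embed(c(numeric(nk - 1), x), nk)
}

# z-transform a series to mean 0, SD 1; errors on zero variance.
z_transform <- function(x, label = "regressor") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("degenerate ", label, ": zero variance, cannot z-transform")
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
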