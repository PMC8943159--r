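#' Generalized Laguerre polynomial of order 2
#'
#' Evaluates \eqn{K_j(x) = \sum_{r=0}^{j} \binom{j+2}{j-r} (-x)^r / r!}, the
#' generalized Laguerre polynomial (associated order 2) underlying the
#' spherical Laguerre function family used for HRF expansion.
#'
#' @param j Non-negative integer polynomial order.
#' @param x Numeric vector of evaluation points.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' laguerre_poly_K(0, 3)   # 1
#' laguerre_poly_K(1, 0)   # 3
#' laguerre_poly_K(2, 1)   # 2.5
#' @export
laguerre_poly_K <- function(j, x) {
  if (length(j) != 1L || !is.finite(j) || j < 0 || j != round(j))
    stop("polynomial order j must be a single non-negative integer")
  if (any(!is.finite(x))) stop("x must be finite")
  r <- 0:j
  coef <- choose(j + 2, j - r) / factorial(r)
  out <- numeric(length(x))
  for (k in seq_along(r))
    out <- out + coef[k] * (-x)^r[k]
  out
}

#' Spherical Laguerre function
#'
#' The j-th spherical Laguerre function
#' \eqn{d_j(n) = \sqrt{j!/(j+2)!}\; e^{-n/(2\alpha)} / \sqrt{\alpha^3}\; K_j(n/\alpha)},
#' an orthonormal-on-\eqn{[0,\infty)} family with exponential decay controlled
#' by the scale `alpha`, suitable for modelling causal finite-memory systems
#' such as the hemodynamic response.
#'
#' @param j Non-negative integer order.
#' @param alpha Positive decay scale, in the units of `n_grid` (seconds).
#' @param n_grid Numeric vector of non-negative time points.
#' @return Numeric vector `d_j(n_grid)`.
#' @export
spherical_laguerre_d <- function(j, alpha, n_grid) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number")
  scale <- sqrt(factorial(j) / factorial(j + 2)) / sqrt(alpha^3)
  scale * exp(-n_grid / (2 * alpha)) * laguerre_poly_K(j, n_grid / alpha)
}

# Discrete Gaussian delay kernel on the dt grid: weights proportional to a
# Gaussian of SD `sigma` seconds centred at delay `tau` seconds, truncated at
# +/- 4 sigma and renormalized to unit sum. Returns the weights and their
# sample offsets (which may start below zero when tau < 4 sigma).
gaussian_delay_kernel <- function(tau, sigma, dt) {
  if (sigma <= 0) stop("sigma must be positive")
  if (tau < 0) stop("tau must be non-negative")
  k0 <- floor((tau - 4 * sigma) / dt)
  k1 <- ceiling((tau + 4 * sigma) / dt)
  k <- k0:k1
  w <- exp(-((k * dt - tau)^2) / (2 * sigma^2))
  list(offsets = k, weights = w / sum(w))
}

#' Build an orthonormal spherical-Laguerre basis set
#'
#' Samples the first `L` spherical Laguerre functions on a `dt` grid of
#' memory `M` samples, convolves each with a discrete Gaussian kernel of SD
#' `sigma` seconds centred at a pure delay `tau` seconds (truncated at
#' \eqn{\pm 4\sigma}, renormalized to unit sum), and orthonormalizes the
#' columns in index order (Gram-Schmidt, computed via QR with a sign-fixed
#' diagonal). The Gaussian step shifts and smooths the basis so the leading
#' functions resemble plausible hemodynamic responses; orthonormalization
#' keeps the subsequent OLS expansion well conditioned.
#'
#' @param L Number of basis functions (>= 1).
#' @param M System memory in samples; the basis covers lags `0..M`.
#' @param alpha Exponential decay scale in seconds.
#' @param tau Pure delay in seconds (>= 0).
#' @param sigma Gaussian SD in seconds (default 1).
#' @param dt Sample spacing in seconds (default 2, a typical TR).
#' @return An object of class `laguerre_basis`: a list with the
#'   `(M+1) x L` orthonormal matrix `B`, the raw smoothed (pre-QR) columns
#'   `B_raw`, and the parameters `L, M, alpha, tau, sigma, dt`.
#' @export
build_basis <- function(L, M, alpha, tau, sigma = 1, dt = 2) {
  if (L < 1 || L != round(L)) stop("L must be a positive integer")
  if (L > M + 1) stop("rank error: L = ", L, " basis functions cannot be ",
                      "orthonormalized on M + 1 = ", M + 1, " samples")
  if (alpha <= 0) stop("alpha must be positive")
  if (dt <= 0) stop("dt must be positive")
  ker <- gaussian_delay_kernel(tau, sigma, dt)
  # evaluate d_j beyond lag M so negative kernel offsets stay defined
  ext <- max(0L, -min(ker$offsets))
  t_ext <- (0:(M + ext)) * dt
  raw <- matrix(0, nrow = M + 1L, ncol = L)
  for (j in seq_len(L)) {
    d <- spherical_laguerre_d(j - 1L, alpha, t_ext)
    col <- numeric(M + 1L)
    for (i in seq_along(ker$offsets)) {
      k <- ker$offsets[i]
      idx <- (0:M) - k               # sample index of d feeding lag n
      ok <- idx >= 0 & idx <= (M + ext)
      col[ok] <- col[ok] + ker$weights[i] * d[idx[ok] + 1L]
    }
    raw[, j] <- col
  }
  qrd <- qr(raw)
  if (qrd$rank < L)
    stop("rank error: smoothed basis columns are rank deficient (rank ",
         qrd$rank, " < L = ", L, ")")
  Q <- qr.Q(qrd)
  s <- sign(diag(qr.R(qrd)))
  s[s == 0] <- 1
  B <- sweep(Q, 2, s, `*`)
  structure(list(B = B, B_raw = raw, L = L, M = M, alpha = alpha, tau = tau,
                 sigma = sigma, dt = dt),
            class = "laguerre_basis")
}

#' @export
print.laguerre_basis <- function(x, ...) {
  cat(sprintf(
    "spherical-Laguerre basis: L = %d, M = %d samples (%.1f s), alpha = %.3g s, tau = %.3g s, sigma = %.3g s, dt = %.3g s\n",
    x$L, x$M, x$M * x$dt, x$alpha, x$tau, x$sigma, x$dt))
  invisible(x)
}

#' Serialize a basis set to a plain-text file
#'
#' Writes the orthonormal matrix as whitespace-separated text preceded by a
#' YAML header (lines prefixed `#`) carrying `L, M, alpha, tau, sigma, dt`.
#'
#' @param basis A `laguerre_basis`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  hdr <- yaml::as.yaml(basis[c("L", "M", "alpha", "tau", "sigma", "dt")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", strsplit(hdr, "\n")[[1]]), con)
  utils::write.table(format(basis$B, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a basis set written by [write_basis()]
#' @param path File path.
#' @return A `laguerre_basis` (without the raw pre-orthogonalization columns).
#' @export
read_basis <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^# ?", "", grep("^#", lines, value = TRUE))
  meta <- yaml::yaml.load(paste(hdr, collapse = "\n"))
  B <- as.matrix(utils::read.table(text = lines[!grepl("^#", lines)]))
  dimnames(B) <- NULL
  structure(c(list(B = B, B_raw = NULL), meta), class = "laguerre_basis")
}
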