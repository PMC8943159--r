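#' Ground-truth HRF curves for simulation
#'
#' Builds a sampled hemodynamic response curve to drive the BOLD simulator
#' and recovery tests. Three shapes are available:
#' \describe{
#'   \item{`double-gamma`}{the canonical difference of two gamma densities
#'     (peak ~5 s, undershoot ~15 s); parameters `a1, b1, a2, b2, ratio`.}
#'   \item{`gamma-with-delay`}{a single gamma density shifted by `delay_s`.}
#'   \item{`laguerre-composed`}{a linear combination `B %*% coef` of a
#'     spherical-Laguerre basis, guaranteeing span membership for tests;
#'     pass `basis` and `coef` in `params`.}
#' }
#' All curves are zero at lag 0 and finitely supported on `0..M` samples.
#'
#' @param shape One of `"double-gamma"`, `"gamma-with-delay"`,
#'   `"laguerre-composed"`.
#' @param params Named list of shape parameters; see Details. `amplitude`
#'   rescales the curve so its largest-magnitude extremum equals it.
#' @param dt Sample spacing, seconds.
#' @param memory_s Curve support, seconds (ignored for laguerre-composed).
#' @return Numeric curve sampled at `0, dt, ..., memory_s`.
#' @export
make_ground_truth_hrf <- function(shape = c("double-gamma", "gamma-with-delay",
                                            "laguerre-composed"),
                                  params = list(), dt = 2, memory_s = 24) {
  shape <- match.arg(shape)
  if (dt <= 0) stop("dt must be positive")
  p <- params
  h <- switch(shape,
    "double-gamma" = {
      a1 <- p$a1 %||% 6; b1 <- p$b1 %||% 1
      a2 <- p$a2 %||% 16; b2 <- p$b2 %||% 1
      ratio <- p$ratio %||% (1 / 6)
      if (a1 <= 0 || b1 <= 0 || a2 <= 0 || b2 <= 0)
        stop("parameter error: gamma dispersion parameters must be positive")
      t <- seq(0, memory_s, by = dt)
      stats::dgamma(t, a1, b1) - ratio * stats::dgamma(t, a2, b2)
    },
    "gamma-with-delay" = {
      a <- p$a %||% 6; b <- p$b %||% 1; delay <- p$delay_s %||% 0
      if (a <= 0 || b <= 0)
        stop("parameter error: gamma dispersion parameters must be positive")
      if (delay < 0) stop("parameter error: delay_s must be non-negative")
      t <- seq(0, memory_s, by = dt)
      stats::dgamma(pmax(t - delay, 0), a, b)
    },
    "laguerre-composed" = {
      if (is.null(p$basis) || is.null(p$coef))
        stop("laguerre-composed shape needs params$basis and params$coef")
      drop(p$basis$B %*% p$coef)
    })
  if (!is.null(p$amplitude)) {
    peak <- max(abs(h))
    if (peak > 0) h <- h * (p$amplitude / peak)
  }
  h
}

#' Ground truth bundle for the BOLD simulator
#'
#' Collects the region HRFs, activation amplitudes, seed-to-target gPPI
#' coupling strengths and the noise model used by [simulate_bold_run()].
#' The noise model is AR(1) (innovation SD `white_sd`, coefficient `ar1`),
#' a linear drift (`drift_per_s` signal units per second) and a sum of
#' sinusoids emulating cardiac/respiratory pseudo-physiology.
#'
#' @param hrf_nov,hrf_rep Sampled HRFs on the TR grid (lag 0..M).
#' @param beta_nov,beta_rep Activation amplitudes applied to task voxels.
#' @param coupling_nov,coupling_rep Condition-specific seed-to-target
#'   coupling strengths for gPPI recovery.
#' @param white_sd AR(1) innovation SD (>= 0).
#' @param ar1 AR(1) coefficient, in (-1, 1).
#' @param drift_per_s Linear drift slope, signal units per second.
#' @param physio_amp,physio_freq Amplitudes and frequencies (Hz) of the
#'   pseudo-physiological sinusoids (equal lengths).
#' @return A `ground_truth` list.
#' @export
make_ground_truth <- function(hrf_nov, hrf_rep, beta_nov = 1, beta_rep = 1,
                              coupling_nov = 0, coupling_rep = 0,
                              white_sd = 1, ar1 = 0.3, drift_per_s = 0,
                              physio_amp = c(0.2, 0.1),
                              physio_freq = c(0.1, 0.25)) {
  if (white_sd < 0) stop("parameter error: white_sd must be >= 0")
  if (abs(ar1) >= 1) stop("parameter error: AR(1) coefficient must lie in (-1, 1)")
  if (any(physio_amp < 0)) stop("parameter error: physio amplitudes must be >= 0")
  if (length(physio_amp) != length(physio_freq))
    stop("physio_amp and physio_freq must have equal length")
  structure(list(hrf_nov = hrf_nov, hrf_rep = hrf_rep,
                 beta_nov = beta_nov, beta_rep = beta_rep,
                 coupling_nov = coupling_nov, coupling_rep = coupling_rep,
                 noise = list(white_sd = white_sd, ar1 = ar1,
                              drift_per_s = drift_per_s,
                              physio_amp = physio_amp,
                              physio_freq = physio_freq)),
            class = "ground_truth")
}
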