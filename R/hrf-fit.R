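#' Build the basis-expansion regressor matrix
#'
#' Convolves each condition indicator series with each of its basis
#' functions (causal convolution truncated to the run length) and appends an
#' intercept column, yielding the design `V` of the linear model
#' `Y = V c + e` whose OLS solution gives the expansion coefficients.
#'
#' @param design A `task_design`.
#' @param basis_nov,basis_rep `laguerre_basis` sets for the two conditions
#'   (usually the same object); `dt` must equal the design TR.
#' @return An `expansion_design` list: matrix `V` (with named columns),
#'   index vectors `cols_nov`, `cols_rep`, `col_intercept`, and `dt`.
#' @export
build_expansion_design <- function(design, basis_nov, basis_rep = basis_nov) {
  if (abs(basis_nov$dt - design$tr_seconds) > 1e-9 ||
      abs(basis_rep$dt - design$tr_seconds) > 1e-9)
    stop("grid error: basis dt must equal the design TR")
  vn <- lag_matrix(design$x1, nrow(basis_nov$B)) %*% basis_nov$B
  vr <- lag_matrix(design$x2, nrow(basis_rep$B)) %*% basis_rep$B
  V <- cbind(vn, vr, 1)
  colnames(V) <- c(paste0("nov_b", seq_len(basis_nov$L)),
                   paste0("rep_b", seq_len(basis_rep$L)), "intercept")
  structure(list(V = V, cols_nov = seq_len(basis_nov$L),
                 cols_rep = basis_nov$L + seq_len(basis_rep$L),
                 col_intercept = ncol(V), dt = design$tr_seconds),
            class = "expansion_design")
}

#' Fit the BOLD expansion model by ordinary least squares
#'
#' Solves `Y = V c + e` by OLS and reports the coefficient vector,
#' residuals, in-sample mse and BIC (`N log(RSS/N) + p log N`).
#'
#' @param y Numeric BOLD series.
#' @param V An `expansion_design` or a plain regressor matrix.
#' @return An `expansion_fit` list: `coefficients`, `fitted`, `residuals`,
#'   `mse`, `bic`, `V`, and the condition column indices when available.
#' @export
fit_bold_model <- function(y, V) {
  ed <- if (inherits(V, "expansion_design")) V else NULL
  Vm <- if (is.null(ed)) as.matrix(V) else ed$V
  if (length(y) != nrow(Vm)) stop("length(y) must match nrow(V)")
  qrd <- qr(Vm)
  if (qrd$rank < ncol(Vm)) {
    dep <- colnames(Vm)[qrd$pivot[(qrd$rank + 1):ncol(Vm)]]
    stop("singularity error: design is rank deficient; collinear column(s): ",
         paste(dep %||% "(unnamed)", collapse = ", "))
  }
  cf <- qr.coef(qrd, y)
  fitted <- drop(Vm %*% cf)
  res <- y - fitted
  n <- length(y); p <- ncol(Vm)
  rss <- sum(res^2)
  structure(list(coefficients = cf, fitted = fitted, residuals = res,
                 mse = rss / n,
                 bic = n * log(max(rss, 1e-300) / n) + p * log(n),
                 V = Vm,
                 cols_nov = ed$cols_nov, cols_rep = ed$cols_rep,
                 col_intercept = ed$col_intercept),
            class = "expansion_fit")
}

#' Reconstruct a condition HRF from an expansion fit
#'
#' Applies `h = B c_condition` and attaches shape summaries (signed peak
#' amplitude, peak latency, FWHM). A numerically zero curve gets amplitude 0
#' and undefined latency/width.
#'
#' @param fit An `expansion_fit` from [fit_bold_model()].
#' @param basis The `laguerre_basis` used for that condition.
#' @param condition `"novelty"` or `"repetition"`.
#' @return An `hrf_estimate` list: `h`, `time`, `condition`, `amplitude`,
#'   `peak_latency`, `fwhm`.
#' @export
reconstruct_hrf <- function(fit, basis, condition = c("novelty", "repetition")) {
  condition <- match.arg(condition)
  cols <- switch(condition, novelty = fit$cols_nov, repetition = fit$cols_rep)
  if (is.null(cols)) stop("key error: fit carries no column map for ", condition)
  h <- drop(basis$B %*% fit$coefficients[cols])
  tm <- (seq_along(h) - 1L) * basis$dt
  if (max(abs(h)) < 1e-14 || diff(range(h)) < 1e-14) {
    sm <- list(amplitude = 0, peak_latency = NA_real_, fwhm = NA_real_)
  } else sm <- hrf_summaries(h, basis$dt)
  structure(list(h = h, time = tm, condition = condition,
                 amplitude = sm$amplitude, peak_latency = sm$peak_latency,
                 fwhm = sm$fwhm),
            class = "hrf_estimate")
}

#' Shape summaries of a sampled HRF
#'
#' Amplitude is the signed value at the extremum of largest magnitude
#' (biphasic curves with dominant negative lobes get negative amplitude);
#' peak latency is its time; FWHM is the width of that lobe at half the peak
#' magnitude, with linear interpolation between samples. When the curve
#' never falls to half height on a side within its support, the support edge
#' bounds the width.
#'
#' @param h Non-constant numeric curve sampled at spacing `dt`.
#' @param dt Sample spacing, seconds.
#' @return List with `amplitude`, `peak_latency`, `fwhm`.
#' @export
hrf_summaries <- function(h, dt) {
  if (diff(range(h)) == 0) stop("degenerate-curve error: constant HRF")
  i <- which.max(abs(h))
  amp <- h[i]
  w <- h * sign(amp)                  # peak lobe upward
  half <- abs(amp) / 2
  cross <- function(dir) {
    # samples from the peak to the half-height crossing in direction dir;
    # bounded by the support edge when the lobe never falls to half height
    j <- i
    repeat {
      k <- j + dir
      if (k < 1 || k > length(w)) return(abs(j - i))
      if (w[k] < half) {
        frac <- (w[j] - half) / (w[j] - w[k])
        return(abs(j - i) + frac)
      }
      j <- k
    }
  }
  left <- cross(-1L)
  right <- cross(1L)
  list(amplitude = amp, peak_latency = (i - 1L) * dt,
       fwhm = (left + right) * dt)
}
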