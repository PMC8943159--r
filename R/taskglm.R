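#' Activation GLM with condition-specific estimated HRFs
#'
#' For each run, the condition indicator series are convolved with their
#' estimated HRFs, the resulting regressors are z-transformed (mean 0,
#' SD 1 per run), and an OLS fit with intercept yields one parameter
#' estimate per condition. The activation contrast is
#' `pe_nov - pe_rep`; with multiple runs, per-run parameter estimates are
#' averaged across runs. Re-fitting with the full reconstructed HRF (rather
#' than reading amplitudes off the curve) uses the entire response shape in
#' the estimate.
#'
#' @param y A BOLD series (single run) or a list of per-run series.
#' @param design A `task_design` or list matching `y`.
#' @param h_nov,h_rep Sampled condition HRFs on the design TR grid.
#' @return List: `pe_nov`, `pe_rep`, `contrast` (run-averaged), and
#'   `per_run` data frame.
#' @export
fit_condition_glm <- function(y, design, h_nov, h_rep) {
  if (!is.list(y)) y <- list(y)
  if (inherits(design, "task_design")) design <- list(design)
  stopifnot(length(y) == length(design))
  per_run <- lapply(seq_along(y), function(k) {
    d <- design[[k]]
    r_nov <- conv_causal(d$x1, h_nov)
    r_rep <- conv_causal(d$x2, h_rep)
    if (stats::sd(r_nov) == 0 || stats::sd(r_rep) == 0)
      stop("degenerate-regressor error: a condition regressor has zero variance")
    X <- cbind(intercept = 1, nov = z_transform(r_nov, "novelty regressor"),
               rep = z_transform(r_rep, "repetition regressor"))
    cf <- qr.coef(qr(X), y[[k]])
    data.frame(run = k, pe_nov = cf["nov"], pe_rep = cf["rep"],
               intercept = cf["intercept"])
  })
  per_run <- do.call(rbind, per_run)
  rownames(per_run) <- NULL
  list(pe_nov = mean(per_run$pe_nov), pe_rep = mean(per_run$pe_rep),
       contrast = mean(per_run$pe_nov - per_run$pe_rep), per_run = per_run)
}

#' Construct the five-regressor gPPI design
#'
#' Builds the generalized psychophysiological interaction design for a seed
#' region: one physiological regressor (the demeaned seed mean series), two
#' psychological regressors (each condition block series convolved with the
#' group-level seed HRF, aligning them with the physiological series in
#' time), and two interaction regressors (elementwise product of each
#' psychological regressor with the physiological one). The interaction is
#' formed at the BOLD level without deconvolution to a neural-level signal;
#' this differs from some gPPI variants that deconvolve the seed first.
#'
#' @param seed_ts Mean BOLD series over the seed mask.
#' @param design A `task_design`.
#' @param group_hrf Group-level seed HRF sampled on the TR grid.
#' @param z_psych Z-transform the psychological regressors before use
#'   (default `FALSE`).
#' @return A `gppi_design` list with the `n x 5` matrix `X` (columns
#'   `physio`, `psych_nov`, `psych_rep`, `inter_nov`, `inter_rep`).
#' @export
build_gppi_design <- function(seed_ts, design, group_hrf, z_psych = FALSE) {
  if (length(seed_ts) != design$n_volumes)
    stop("seed series length must match the design")
  physio <- seed_ts - mean(seed_ts)
  psych_nov <- conv_causal(design$x1, group_hrf)
  psych_rep <- conv_causal(design$x2, group_hrf)
  if (z_psych) {
    psych_nov <- z_transform(psych_nov, "psych_nov")
    psych_rep <- z_transform(psych_rep, "psych_rep")
  }
  X <- cbind(physio = physio, psych_nov = psych_nov, psych_rep = psych_rep,
             inter_nov = psych_nov * physio, inter_rep = psych_rep * physio)
  structure(list(X = X, z_psych = z_psych), class = "gppi_design")
}

#' Fit the gPPI model to a target series
#'
#' OLS of the target on an intercept plus the five gPPI regressors. The
#' functional-connectivity contrast is the difference between the two
#' interaction parameter estimates, `pe_inter_nov - pe_inter_rep`. A high
#' design condition number (psychological and interaction terms can be
#' nearly collinear for some seeds) triggers a warning.
#'
#' @param y_target Target BOLD series (e.g. a voxel or ROI mean).
#' @param gppi_design A [build_gppi_design()] object.
#' @param kappa_warn Condition-number threshold for the collinearity warning.
#' @return List: `pe` (named coefficients), `pe_inter_nov`, `pe_inter_rep`,
#'   `fc_contrast`, `fitted`.
#' @export
fit_gppi <- function(y_target, gppi_design, kappa_warn = 1e6) {
  X <- cbind(intercept = 1, gppi_design$X)
  if (length(y_target) != nrow(X)) stop("target series length must match design")
  kap <- kappa(X, exact = FALSE)
  if (is.finite(kap) && kap > kappa_warn)
    warning(sprintf("gPPI design condition number %.3g exceeds %.3g", kap, kappa_warn))
  qrd <- qr(X)
  if (qrd$rank < ncol(X))
    stop("singularity error: degenerate gPPI design")
  cf <- qr.coef(qrd, y_target)
  list(pe = cf, pe_inter_nov = unname(cf["inter_nov"]),
       pe_inter_rep = unname(cf["inter_rep"]),
       fc_contrast = unname(cf["inter_nov"] - cf["inter_rep"]),
       fitted = drop(X %*% cf))
}
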