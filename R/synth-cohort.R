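#' Two-component Gaussian mixture for amyloid burden (PiB DVR)
#'
#' Models the distribution of amyloid PET distribution volume ratios as a
#' mixture of a low-burden and a high-burden Gaussian component. The weight
#' of the high component is solved analytically so that the mixture mass
#' above the positivity cut-off (1.324 DVR, partial-volume-corrected scale)
#' equals the requested amyloid-positive fraction; the default fraction,
#' 36/128, emulates the prevalence of elevated amyloid among cognitively
#' unimpaired older cohorts.
#'
#' @param positive_fraction Target mass above the cut-off.
#' @param cutoff Positivity threshold on the DVR scale.
#' @param mean_low,sd_low,mean_high,sd_high Component parameters.
#' @return An `amyloid_mixture` list with the solved component weight.
#' @export
default_amyloid_mixture <- function(positive_fraction = 36 / 128,
                                    cutoff = 1.324,
                                    mean_low = 1.10, sd_low = 0.05,
                                    mean_high = 1.60, sd_high = 0.15) {
  if (sd_low <= 0 || sd_high <= 0) stop("parameter error: component SDs must be positive")
  p_low <- stats::pnorm(cutoff, mean_low, sd_low, lower.tail = FALSE)
  p_high <- stats::pnorm(cutoff, mean_high, sd_high, lower.tail = FALSE)
  if (positive_fraction < p_low || positive_fraction > p_high)
    stop("parameter error: requested positive fraction unreachable with these components")
  w_high <- (positive_fraction - p_low) / (p_high - p_low)
  structure(list(mean_low = mean_low, sd_low = sd_low,
                 mean_high = mean_high, sd_high = sd_high,
                 w_high = w_high, cutoff = cutoff),
            class = "amyloid_mixture")
}

#' Analytic amyloid-positive fraction of a mixture
#'
#' Mass of the DVR mixture above the positivity cut-off.
#'
#' @param mixture An [default_amyloid_mixture()] object.
#' @param cutoff Threshold; defaults to the mixture's own.
#' @return Scalar in \[0, 1\].
#' @export
amyloid_positive_fraction <- function(mixture, cutoff = mixture$cutoff) {
  (1 - mixture$w_high) * stats::pnorm(cutoff, mixture$mean_low, mixture$sd_low,
                                      lower.tail = FALSE) +
    mixture$w_high * stats::pnorm(cutoff, mixture$mean_high, mixture$sd_high,
                                  lower.tail = FALSE)
}

#' Default fixed-effect coefficients for the longitudinal outcome model
#'
#' Named vector of the coefficients of the longitudinal mixed model:
#' intercept, baseline covariate main effects (age, sex, education), the two
#' predictors of interest (imaging predictor `predA`, amyloid DVR `predB`),
#' covariate-by-time interactions, predictor-by-time interactions, and the
#' three-way predictor-by-amyloid-by-time interaction. Two extra optional
#' terms (`time`, `predA:predB`) default to zero: the generating model
#' carries time effects through the interactions and the random slope.
#'
#' @param ... Named overrides, e.g. `beta_ab_time = 0.2`.
#' @return Named numeric vector of 14 coefficients.
#' @export
eq_betas <- function(...) {
  b <- c(beta0 = 0, beta_age = 0, beta_sex = 0, beta_edu = 0,
         beta_a = 0, beta_b = 0,
         beta_age_time = 0, beta_sex_time = 0, beta_edu_time = 0,
         beta_a_time = 0, beta_b_time = 0, beta_ab_time = 0,
         beta_time = 0, beta_ab = 0)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(b))
    if (length(bad)) stop("unknown coefficient(s): ", paste(bad, collapse = ", "))
    b[names(over)] <- over
  }
  b
}

#' Simulate a longitudinal cohort with planted effects
#'
#' Draws per-subject covariates (baseline age ~ N(70, 8) years, sex as a 0/1
#' code, education uniform on 12..20 integer years), an imaging predictor
#' `predA ~ N(0, 1)`, and amyloid DVR `predB` from the two-component mixture
#' (values truncated to be positive; a dichotomous `amyloid_pos` flag is
#' attached at the 1.324 cut-off). Outcomes follow the linear mixed model
#' with subject random intercepts and time slopes (correlation `rho`) and
#' i.i.d. Gaussian residuals:
#' \deqn{y_{ij} = \beta_0 + \beta_{age}Age_i + ... +
#'   \beta_{ab,time} PredA_i PredB_i Time_{ij} + b_{0i} + b_{si}Time_{ij} + e_{ij}.}
#'
#' @param n_subjects Number of subjects.
#' @param betas Coefficients from [eq_betas()].
#' @param random_sd Length-2 vector: SD of the random intercept and of the
#'   random time slope.
#' @param rho Correlation between random intercept and slope.
#' @param resid_sd Residual SD.
#' @param amyloid_mixture DVR mixture, [default_amyloid_mixture()].
#' @param predA_values Optional length-`n_subjects` vector of imaging
#'   predictor values to use instead of drawing `predA ~ N(0, 1)` (e.g. the
#'   measured activation contrasts).
#' @param visit_times Baseline-anchored visit times in years (time 0 must be
#'   included); per-subject dropout keeps each subject's first
#'   `>= min_visits` visits with probability `retention` per later visit.
#' @param retention Per-visit retention probability after baseline.
#' @param min_visits Minimum visits retained per subject.
#' @param seed Integer seed.
#' @return A long-format data frame (class `longitudinal_cohort`): subject,
#'   time (years), outcome, age, sex, edu, predA, predB, amyloid_pos.
#' @export
simulate_cohort <- function(n_subjects = 128, betas = eq_betas(),
                            random_sd = c(1, 0.3), rho = 0,
                            resid_sd = 0.5,
                            amyloid_mixture = default_amyloid_mixture(),
                            predA_values = NULL,
                            visit_times = c(0, 1, 2, 3, 4),
                            retention = 1, min_visits = 1, seed = 1) {
  if (any(random_sd < 0) || resid_sd < 0)
    stop("parameter error: variance components must be non-negative")
  if (abs(rho) > 1) stop("parameter error: |rho| must be <= 1")
  if (!any(visit_times == 0)) stop("visit_times must include baseline time 0")
  b <- eq_betas()
  if (length(betas)) {
    if (is.null(names(betas)) || any(!names(betas) %in% names(b)))
      stop("betas must be a named subset of eq_betas()")
    b[names(betas)] <- betas
  }
  with_seed(seed, {
    age <- stats::rnorm(n_subjects, 70, 8)
    sex <- stats::rbinom(n_subjects, 1, 0.5)
    edu <- sample(12:20, n_subjects, replace = TRUE)
    predA <- if (is.null(predA_values)) stats::rnorm(n_subjects) else {
      stopifnot(length(predA_values) == n_subjects)
      predA_values
    }
    comp <- stats::rbinom(n_subjects, 1, amyloid_mixture$w_high)
    predB <- ifelse(comp == 1,
                    stats::rnorm(n_subjects, amyloid_mixture$mean_high,
                                 amyloid_mixture$sd_high),
                    stats::rnorm(n_subjects, amyloid_mixture$mean_low,
                                 amyloid_mixture$sd_low))
    while (any(predB <= 0))
      predB[predB <= 0] <- stats::rnorm(sum(predB <= 0),
                                        amyloid_mixture$mean_low,
                                        amyloid_mixture$sd_low)
    # correlated random intercept/slope
    z1 <- stats::rnorm(n_subjects); z2 <- stats::rnorm(n_subjects)
    b0i <- random_sd[1] * z1
    bsi <- random_sd[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
    rows <- lapply(seq_len(n_subjects), function(i) {
      keep <- c(TRUE, stats::runif(length(visit_times) - 1) <= retention)
      keep[seq_len(min(min_visits, length(visit_times)))] <- TRUE
      tm <- sort(visit_times[keep])
      mu <- b["beta0"] + b["beta_age"] * age[i] + b["beta_sex"] * sex[i] +
        b["beta_edu"] * edu[i] + b["beta_a"] * predA[i] + b["beta_b"] * predB[i] +
        b["beta_ab"] * predA[i] * predB[i] +
        (b["beta_time"] + b["beta_age_time"] * age[i] +
           b["beta_sex_time"] * sex[i] + b["beta_edu_time"] * edu[i] +
           b["beta_a_time"] * predA[i] + b["beta_b_time"] * predB[i] +
           b["beta_ab_time"] * predA[i] * predB[i]) * tm
      y <- mu + b0i[i] + bsi[i] * tm + stats::rnorm(length(tm), sd = resid_sd)
      data.frame(subject = i, time = tm, outcome = as.numeric(y),
                 age = age[i], sex = sex[i], edu = edu[i],
                 predA = predA[i], predB = predB[i])
    })
    out <- do.call(rbind, rows)
    out$amyloid_pos <- as.integer(out$predB > amyloid_mixture$cutoff)
    class(out) <- c("longitudinal_cohort", "data.frame")
    out
  })
}
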