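#' Specify a longitudinal mixed-effects model
#'
#' Defines the fixed-effect structure of the voxel-wise longitudinal model.
#' `model = "i"` is the two-way moderation model
#' `outcome ~ predA * time + covariates`; `model = "ii"` adds the amyloid
#' moderator with the full three-way factorial `predA * predB * time`
#' (including all lower-order terms). Baseline age, sex and education enter
#' as covariates, optionally with time interactions that can be pruned when
#' non-significant. Random structure is a subject random intercept plus a
#' random time slope, falling back to intercept-only when the slope variance
#' converges to the boundary.
#'
#' @param model `"i"` (predictor-by-time) or `"ii"`
#'   (predictor-by-amyloid-by-time).
#' @param pib `"continuous"` (DVR) or `"dichotomous"` (cut-off flag).
#' @param covariate_time Include covariate-by-time interactions initially.
#' @param prune_p Drop a covariate-by-time term when its p-value exceeds
#'   this (default 0.10) ...
#' @param prune_change ... provided the remaining estimates change by less
#'   than this relative amount (default 0.10) after removal.
#' @return An `lme_spec` list.
#' @export
lme_spec <- function(model = c("ii", "i"), pib = c("continuous", "dichotomous"),
                     covariate_time = TRUE, prune_p = 0.10,
                     prune_change = 0.10) {
  structure(list(model = match.arg(model), pib = match.arg(pib),
                 covariate_time = covariate_time, prune_p = prune_p,
                 prune_change = prune_change),
            class = "lme_spec")
}

lme_formula <- function(spec, covariate_time = spec$covariate_time,
                        random = c("slope", "intercept")) {
  random <- match.arg(random)
  fixed <- if (spec$model == "ii") "predA * predB * time" else "predA * time"
  cov <- "age + sex + edu"
  if (covariate_time) cov <- paste(cov, "+ age:time + sex:time + edu:time")
  re <- if (random == "slope") "(1 + time | subject)" else "(1 | subject)"
  stats::as.formula(paste("outcome ~", fixed, "+", cov, "+", re))
}

# Fixed-effect table (estimate, se, Wald z, p) from a merMod fit.
fixef_table <- function(fit) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))))
}

#' Fit the longitudinal mixed-effects model to a cohort
#'
#' Maximum-likelihood fit of the [lme_spec()] model with subject random
#' intercepts and time slopes. When the random-slope variance converges to
#' the boundary (singular fit), the model is refitted with a random
#' intercept only. Covariate-by-time interactions with p above
#' `spec$prune_p` are removed and the model refitted, provided the
#' remaining estimates change by less than `spec$prune_change` (relative);
#' otherwise the unpruned fit is kept.
#'
#' @param cohort Long-format data frame with columns `subject`, `time`,
#'   `outcome`, `age`, `sex`, `edu`, `predA`, and (model ii) `predB` or
#'   `amyloid_pos`.
#' @param spec An [lme_spec()].
#' @return An `lme_fit` list: `fit` (merMod), `table` (fixed effects with
#'   Wald z), `spec`, `random` ("slope" or "intercept"), `pruned` (dropped
#'   terms).
#' @export
fit_lme_cohort <- function(cohort, spec = lme_spec()) {
  d <- as.data.frame(cohort)
  if (spec$model == "ii") {
    if (spec$pib == "dichotomous") d$predB <- as.numeric(d$amyloid_pos)
    if (is.null(d$predB)) stop("cohort lacks the amyloid predictor")
  }
  fit_one <- function(form) {
    suppressMessages(lme4::lmer(form, data = d, REML = FALSE,
                                control = lme4::lmerControl(
                                  calc.derivs = FALSE,
                                  check.scaleX = "ignore",
                                  check.conv.singular = "ignore")))
  }
  fit_with_fallback <- function(covariate_time) {
    f <- fit_one(lme_formula(spec, covariate_time, "slope"))
    random <- "slope"
    if (lme4::isSingular(f, tol = 1e-4)) {
      f <- fit_one(lme_formula(spec, covariate_time, "intercept"))
      random <- "intercept"
    }
    list(fit = f, random = random)
  }
  full <- fit_with_fallback(spec$covariate_time)
  tab <- fixef_table(full$fit)
  pruned <- character()
  result <- full
  if (spec$covariate_time) {
    ct_terms <- grep("^(time:(age|sex|edu)|(age|sex|edu):time)$", tab$term,
                     value = TRUE)
    drop_terms <- ct_terms[tab$p[match(ct_terms, tab$term)] > spec$prune_p]
    if (length(drop_terms) == length(ct_terms) && length(ct_terms) > 0) {
      reduced <- fit_with_fallback(covariate_time = FALSE)
      rtab <- fixef_table(reduced$fit)
      # "did not change the effect of other predictors": guard the terms
      # involving the predictors of interest, not every nuisance estimate
      common <- grep("predA|predB",
                     setdiff(intersect(tab$term, rtab$term), ct_terms),
                     value = TRUE)
      a <- tab$estimate[match(common, tab$term)]
      bb <- rtab$estimate[match(common, rtab$term)]
      rel <- abs(bb - a) / pmax(abs(a), 1e-8)
      if (all(rel < spec$prune_change)) {
        result <- reduced
        tab <- rtab
        pruned <- ct_terms
      }
    }
  }
  structure(list(fit = result$fit, table = tab, spec = spec,
                 random = result$random, pruned = pruned),
            class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf("longitudinal LME (model %s, random %s%s)\n", x$spec$model,
              x$random,
              if (length(x$pruned)) paste0("; pruned: ",
                                           paste(x$pruned, collapse = ", "))
              else ""))
  print(x$table, digits = 4)
  invisible(x)
}

#' Voxel-wise longitudinal mixed-effects mapping
#'
#' Fits the [lme_spec()] model independently at every voxel (or ROI), using
#' that voxel's subject-level contrast value as the imaging predictor
#' `predA`. Voxels whose fit fails even after the intercept-only fallback
#' are flagged missing rather than aborting the map.
#'
#' @param contrast_mat Subjects-by-voxels matrix of contrast estimates;
#'   row order must match `unique(cohort$subject)`.
#' @param cohort Long-format cohort (see [fit_lme_cohort()]).
#' @param spec An [lme_spec()].
#' @param term The fixed-effect term whose Z map is of interest; default is
#'   the highest-order interaction of the model.
#' @return List: `estimate`, `se`, `z` (numeric per voxel, NA when failed),
#'   `term`, `failed` (indices).
#' @export
fit_voxelwise_lme <- function(contrast_mat, cohort, spec = lme_spec(),
                              term = NULL) {
  subjects <- unique(cohort$subject)
  if (nrow(contrast_mat) != length(subjects))
    stop("contrast_mat must have one row per cohort subject")
  if (is.null(term))
    term <- if (spec$model == "ii") "predA:predB:time" else "predA:time"
  nv <- ncol(contrast_mat)
  est <- se <- z <- rep(NA_real_, nv)
  for (v in seq_len(nv)) {
    cohort$predA <- contrast_mat[match(cohort$subject, subjects), v]
    res <- tryCatch(fit_lme_cohort(cohort, spec), error = function(e) NULL)
    if (is.null(res)) next
    i <- match(term, res$table$term)
    if (is.na(i)) next
    est[v] <- res$table$estimate[i]
    se[v] <- res$table$se[i]
    z[v] <- res$table$z[i]
  }
  list(estimate = est, se = se, z = z, term = term,
       failed = which(is.na(z)))
}

# Coefficients and covariance from lm / merMod / lme_fit, uniformly.
coef_vcov <- function(fit) {
  if (inherits(fit, "lme_fit")) fit <- fit$fit
  if (inherits(fit, "merMod"))
    list(coef = lme4::fixef(fit), vcov = as.matrix(stats::vcov(fit)))
  else list(coef = stats::coef(fit), vcov = stats::vcov(fit))
}

#' Simple slopes of the time effect at chosen moderator levels
#'
#' For a fitted moderation model, the conditional (simple) slope at
#' moderator value `m` is the linear combination
#' `beta[base_term] + m * beta[inter_term]`, with standard error from the
#' corresponding quadratic form of the coefficient covariance. Default
#' levels are the moderator mean and mean +/- 1 SD.
#'
#' @param fit An `lme_fit`, `merMod` or `lm` object.
#' @param base_term Name of the base slope coefficient (e.g. `"predA:time"`).
#' @param inter_term Name of the moderating interaction coefficient (e.g.
#'   `"predA:predB:time"`).
#' @param levels Moderator values; or supply `moderator` values to use
#'   mean and +/- 1 SD.
#' @param moderator Optional raw moderator values from which default levels
#'   are computed.
#' @return Data frame: `level`, `estimate`, `se`, `z`, `p`.
#' @export
simple_slopes <- function(fit, base_term, inter_term, levels = NULL,
                          moderator = NULL) {
  cv <- coef_vcov(fit)
  if (!(base_term %in% names(cv$coef)))
    stop("specification error: term '", base_term, "' not in the model")
  if (!(inter_term %in% names(cv$coef)))
    stop("specification error: term '", inter_term, "' not in the model")
  if (is.null(levels)) {
    if (is.null(moderator))
      stop("provide moderator levels or raw moderator values")
    levels <- mean(moderator) + c(-1, 0, 1) * stats::sd(moderator)
  }
  ib <- match(base_term, names(cv$coef))
  ii <- match(inter_term, names(cv$coef))
  out <- lapply(levels, function(m) {
    est <- cv$coef[ib] + m * cv$coef[ii]
    v <- cv$vcov[ib, ib] + 2 * m * cv$vcov[ib, ii] + m^2 * cv$vcov[ii, ii]
    se <- sqrt(v)
    z <- est / se
    data.frame(level = m, estimate = unname(est), se = se,
               z = unname(z), p = 2 * stats::pnorm(-abs(unname(z))))
  })
  do.call(rbind, out)
}

#' Floodlight (Johnson-Neyman) analysis over a moderator grid
#'
#' Evaluates the conditional slope and its Wald test at every point of a
#' moderator grid, adjusts the p-values across grid points by
#' Benjamini-Hochberg FDR (optional), and reports the significance region
#' and its smallest moderator value — the lower bound of the range where
#' the predictor-by-time association is detectable.
#'
#' @param fit Fitted model (see [simple_slopes()]).
#' @param base_term,inter_term Coefficient names as in [simple_slopes()].
#' @param grid Numeric moderator grid spanning the observed range.
#' @param alpha Significance level.
#' @param fdr Apply BH adjustment across grid points (default `TRUE`).
#' @return A `floodlight_result` list: `grid`, `estimate`, `se`, `p`,
#'   `p_adj`, `significant` (logical), `lower_bound` (NA when empty).
#' @export
floodlight <- function(fit, base_term, inter_term, grid, alpha = 0.05,
                       fdr = TRUE) {
  if (!length(grid)) stop("configuration error: empty moderator grid")
  ss <- simple_slopes(fit, base_term, inter_term, levels = grid)
  p_adj <- if (fdr) stats::p.adjust(ss$p, method = "BH") else ss$p
  sig <- p_adj <= alpha
  structure(list(grid = grid, estimate = ss$estimate, se = ss$se,
                 p = ss$p, p_adj = p_adj, significant = sig,
                 lower_bound = if (any(sig)) min(grid[sig]) else NA_real_),
            class = "floodlight_result")
}

#' @export
print.floodlight_result <- function(x, ...) {
  cat(sprintf("floodlight: %d/%d grid points significant; lower bound %s\n",
              sum(x$significant), length(x$grid),
              if (is.na(x$lower_bound)) "none" else format(x$lower_bound)))
  invisible(x)
}
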