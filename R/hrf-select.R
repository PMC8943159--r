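#' Cross-validated generalization error of the expansion model
#'
#' Leave-one-run-out cross-validation: for each held-out run the model is
#' fitted by OLS on the remaining runs (stacked), the held-out run is
#' predicted, and the mean squared prediction error
#' \eqn{mse = N^{-1}\sum_n (\hat y(n) - y(n))^2} is computed; the
#' generalization error is the average mse across folds.
#'
#' @param y_set List of BOLD series, one per run.
#' @param design_set List of `task_design`s matching `y_set`.
#' @param L Basis order shared by both conditions.
#' @param alpha,tau Basis decay scale and pure delay, seconds.
#' @param memory_s Basis memory in seconds (default 24).
#' @param sigma Gaussian kernel SD, seconds.
#' @param V_set Optional precomputed list of `expansion_design`s for these
#'   runs (skips basis construction; used by the grid search).
#' @return Scalar cross-validated mse.
#' @export
cv_generalization_error <- function(y_set, design_set, L, alpha, tau,
                                    memory_s = 24, sigma = 1, V_set = NULL) {
  if (length(y_set) < 2) stop("fold error: leave-one-run-out needs >= 2 runs")
  if (length(y_set) != length(design_set)) stop("y_set and design_set lengths differ")
  if (is.null(V_set)) {
    dt <- design_set[[1]]$tr_seconds
    basis <- build_basis(L, round(memory_s / dt), alpha, tau, sigma, dt)
    V_set <- lapply(design_set, build_expansion_design, basis_nov = basis)
  }
  # per-run normal equations make the leave-one-run-out loop cheap:
  # training Gram/moment matrices are totals minus the held-out run's
  G <- lapply(V_set, function(e) crossprod(e$V))
  bvec <- mapply(function(e, y) crossprod(e$V, y), V_set, y_set,
                 SIMPLIFY = FALSE)
  Gtot <- Reduce(`+`, G)
  btot <- Reduce(`+`, bvec)
  mean(vapply(seq_along(y_set), function(k) {
    cf <- solve(Gtot - G[[k]], btot - bvec[[k]])
    pred <- drop(V_set[[k]]$V %*% cf)
    mean((pred - y_set[[k]])^2)
  }, numeric(1)))
}

#' Grid search for the basis decay and delay parameters
#'
#' Evaluates the leave-one-run-out generalization error on every point of
#' the `(alpha, tau)` grid for each ROI series set, averages the error
#' across ROIs, and returns the minimizing grid point. Ties (within a
#' relative tolerance of 1e-10) are broken in favour of smaller `tau`, then
#' smaller `alpha`. The full error surface is returned for diagnostics.
#'
#' @param y_roi_set Either a list of per-run series for a single ROI, or a
#'   list of such lists (one per ROI).
#' @param design_set List of `task_design`s (shared across ROIs).
#' @param L Basis order.
#' @param alpha_grid,tau_grid Candidate values in seconds. Defaults cover
#'   canonical HRF dynamics: alpha 0.25..3 s by 0.25, tau 0..4 s by 0.5.
#' @param memory_s,sigma Basis construction parameters.
#' @return List: `alpha`, `tau`, `error` (at the optimum), and `surface`
#'   (matrix alpha x tau of ROI-averaged cv errors).
#' @export
grid_search_basis <- function(y_roi_set, design_set, L = 2,
                              alpha_grid = seq(0.25, 3, by = 0.25),
                              tau_grid = seq(0, 4, by = 0.5),
                              memory_s = 24, sigma = 1) {
  if (!length(alpha_grid) || !length(tau_grid)) stop("empty parameter grid")
  if (!length(y_roi_set)) stop("y_roi_set is empty")
  if (is.numeric(y_roi_set[[1]])) y_roi_set <- list(y_roi_set)
  dt <- design_set[[1]]$tr_seconds
  M <- round(memory_s / dt)
  surface <- matrix(NA_real_, length(alpha_grid), length(tau_grid),
                    dimnames = list(alpha_grid, tau_grid))
  for (ia in seq_along(alpha_grid)) for (it in seq_along(tau_grid)) {
    basis <- build_basis(L, M, alpha_grid[ia], tau_grid[it], sigma, dt)
    V_set <- lapply(design_set, build_expansion_design, basis_nov = basis)
    errs <- vapply(y_roi_set, function(ys)
      cv_generalization_error(ys, design_set, L, alpha_grid[ia], tau_grid[it],
                              memory_s, sigma, V_set = V_set), numeric(1))
    surface[ia, it] <- mean(errs)
  }
  if (all(is.na(surface))) stop("estimation error: all-NaN error surface")
  best <- min(surface, na.rm = TRUE)
  tol <- 1e-10 * max(1, abs(best))
  cand <- which(surface <= best + tol, arr.ind = TRUE)
  ord <- order(tau_grid[cand[, 2]], alpha_grid[cand[, 1]])
  pick <- cand[ord[1], ]
  list(alpha = alpha_grid[pick[1]], tau = tau_grid[pick[2]],
       error = surface[pick[1], pick[2]], surface = surface)
}

#' Select the basis model order by BIC
#'
#' Fits the stacked-run expansion model for each candidate order (shared by
#' both conditions) at fixed `(alpha, tau)` and returns the BIC-minimizing
#' order; ties go to the smaller order.
#'
#' @param y_set,design_set Per-run series and designs.
#' @param alpha,tau Basis parameters, seconds.
#' @param L_candidates Candidate orders (subset of 1..6).
#' @param memory_s,sigma Basis construction parameters.
#' @return List: `L` (selected order), `bic` (named vector over candidates).
#' @export
select_model_order <- function(y_set, design_set, alpha, tau,
                               L_candidates = 1:4, memory_s = 24, sigma = 1) {
  if (!length(L_candidates)) stop("configuration error: empty candidate set")
  L_candidates <- sort(unique(as.integer(L_candidates)))
  dt <- design_set[[1]]$tr_seconds
  M <- round(memory_s / dt)
  y <- unlist(y_set, use.names = FALSE)
  bic <- vapply(L_candidates, function(L) {
    basis <- build_basis(L, M, alpha, tau, sigma, dt)
    V <- do.call(rbind, lapply(design_set, function(d)
      build_expansion_design(d, basis)$V))
    fit_bold_model(y, V)$bic
  }, numeric(1))
  names(bic) <- L_candidates
  list(L = L_candidates[which.min(bic)], bic = bic)
}

#' Two-step subject-level HRF estimation
#'
#' Step one selects the subject's basis by grid search over `(alpha, tau)`
#' using the ROI-averaged leave-one-run-out generalization error; step two
#' fits the stacked-run expansion model with the selected basis to each
#' target series and reconstructs the condition HRFs.
#'
#' @param y_roi_set ROI series used for parameter selection (list of per-run
#'   series, or list of such lists over ROIs).
#' @param y_target_set Series to estimate HRFs for: list of per-run series
#'   (a single target) or list of targets.
#' @param design_set Per-run designs.
#' @param L Basis order (default 2).
#' @param ... Passed to [grid_search_basis()].
#' @return List: `alpha`, `tau`, `basis`, `surface`, and `estimates` — per
#'   target a list with `fit`, `hrf_nov`, `hrf_rep`.
#' @export
estimate_hrf_twostep <- function(y_roi_set, y_target_set, design_set, L = 2, ...) {
  gs <- grid_search_basis(y_roi_set, design_set, L = L, ...)
  dots <- list(...)
  memory_s <- dots$memory_s %||% 24
  sigma <- dots$sigma %||% 1
  dt <- design_set[[1]]$tr_seconds
  basis <- build_basis(L, round(memory_s / dt), gs$alpha, gs$tau, sigma, dt)
  V_set <- lapply(design_set, build_expansion_design, basis_nov = basis)
  Vall <- do.call(rbind, lapply(V_set, `[[`, "V"))
  ed_proto <- V_set[[1]]
  if (is.numeric(y_target_set[[1]])) y_target_set <- list(y_target_set)
  estimates <- lapply(y_target_set, function(ys) {
    fit <- fit_bold_model(unlist(ys, use.names = FALSE), Vall)
    fit$cols_nov <- ed_proto$cols_nov
    fit$cols_rep <- ed_proto$cols_rep
    fit$col_intercept <- ed_proto$col_intercept
    list(fit = fit,
         hrf_nov = reconstruct_hrf(fit, basis, "novelty"),
         hrf_rep = reconstruct_hrf(fit, basis, "repetition"))
  })
  list(alpha = gs$alpha, tau = gs$tau, basis = basis, surface = gs$surface,
       estimates = estimates)
}

#' Group-level HRF shape via the first principal component
#'
#' The common shape of a set of HRF estimates is summarized by the first
#' principal direction of the (uncentred) curve matrix, computed by SVD.
#' The sign is fixed so the largest-magnitude extremum of the component is
#' positive. The explained-variance fraction is the share of the first
#' squared singular value.
#'
#' @param h_list List of sampled curves of equal length (or a matrix with
#'   one curve per row).
#' @return List: `curve` (unit norm), `explained_variance`.
#' @export
group_hrf_shape <- function(h_list) {
  if (is.list(h_list)) {
    if (length(h_list) < 2) stop("need >= 2 curves")
    len <- lengths(h_list)
    if (length(unique(len)) != 1) stop("shape error: curves have unequal lengths")
    X <- do.call(rbind, h_list)
  } else X <- as.matrix(h_list)
  s <- svd(X)
  pc1 <- s$v[, 1]
  i <- which.max(abs(pc1))
  if (pc1[i] < 0) pc1 <- -pc1
  list(curve = pc1, explained_variance = s$d[1]^2 / sum(s$d^2))
}
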