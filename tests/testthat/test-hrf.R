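test_that("expansion design columns are causal convolutions of the indicators", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(1)[[1]]
  ed <- build_expansion_design(ds, fx$basis)
  # brute-force convolution oracle
  for (j in 1:2) {
    expect_lt(max(abs(ed$V[, j] - conv_causal2(ds$x1, fx$basis$B[, j]))), 1e-10)
    expect_lt(max(abs(ed$V[, 2 + j] - conv_causal2(ds$x2, fx$basis$B[, j]))), 1e-10)
  }
  expect_identical(unname(ed$V[, 5]), rep(1, ds$n_volumes))
  # impulse design: columns are the padded basis functions
  imp <- ds
  imp$x1 <- c(1, numeric(ds$n_volumes - 1)); imp$x2 <- numeric(ds$n_volumes)
  edi <- build_expansion_design(imp, fx$basis)
  expect_equal(edi$V[1:13, 1], fx$basis$B[, 1], tolerance = 1e-12)
  expect_identical(max(abs(edi$V[, 3:4])), 0)
  # dt mismatch is rejected
  b05 <- build_basis(2, 48, 1.5, 1, 1, 0.5)
  expect_error(build_expansion_design(ds, b05), "grid error")
})

test_that("OLS fit recovers noiseless coefficients and satisfies orthogonality", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(2)
  ed <- build_expansion_design(ds[[1]], fx$basis)
  c0 <- c(1, 0.4, 0.6, 0.1, 2)
  y <- drop(ed$V %*% c0)
  fit <- fit_bold_model(y, ed)
  expect_lt(max(abs(fit$coefficients - c0)), 1e-10)
  yn <- y + with_seed2(1, rnorm(length(y)))
  fitn <- fit_bold_model(yn, ed)
  expect_lt(max(abs(crossprod(fitn$V, fitn$residuals))),
            1e-8 * max(abs(yn)))
  # orthonormal design: coefficients are plain projections
  Q <- qr.Q(qr(ed$V))
  fq <- fit_bold_model(yn, Q)
  expect_equal(unname(fq$coefficients), drop(crossprod(Q, yn)),
               tolerance = 1e-12)
  expect_error(fit_bold_model(y, cbind(ed$V, ed$V[, 1])), "singularity")
})

test_that("coefficient sampling covariance matches the OLS closed form", {
  fx <- fixture_span_hrfs()
  ed <- build_expansion_design(fixture_designs(1)[[1]], fx$basis)
  sigma_w <- 0.8
  G <- solve(crossprod(ed$V)) * sigma_w^2
  chat <- with_seed2(42, vapply(1:1000, function(i)
    fit_bold_model(rnorm(nrow(ed$V), sd = sigma_w), ed)$coefficients,
    numeric(ncol(ed$V))))
  emp <- cov(t(chat))
  scale <- sqrt(diag(G) %o% diag(G))
  expect_lt(max(abs(emp - G) / scale), 0.15)
})

test_that("HRF reconstruction inverts the expansion", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(2)
  ed <- build_expansion_design(ds[[1]], fx$basis)
  y <- drop(ed$V %*% c(1, 0, 0, 0, 0))
  fit <- fit_bold_model(y, ed)
  h <- reconstruct_hrf(fit, fx$basis, "novelty")
  expect_equal(h$h, fx$basis$B[, 1], tolerance = 1e-10)
  h0 <- reconstruct_hrf(fit_bold_model(numeric(nrow(ed$V)), ed),
                        fx$basis, "repetition")
  expect_identical(h0$amplitude, 0)
  expect_identical(max(abs(h0$h)), 0)
  # span membership: noiseless fit reconstructs the generating HRF exactly
  y2 <- drop(ed$V %*% c(1, 0.5, 0.6, 0.3, 0))
  fit2 <- fit_bold_model(y2, ed)
  expect_gt(cor(reconstruct_hrf(fit2, fx$basis, "novelty")$h, fx$h_nov),
            1 - 1e-8)
})

test_that("cross-validated error finds the noise floor and the truth", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(6)
  # noiseless, correct basis: error at machine precision
  ys0 <- lapply(ds, function(d)
    conv_causal2(d$x1, fx$h_nov) + conv_causal2(d$x2, fx$h_rep))
  expect_lt(cv_generalization_error(ys0, ds, 2, fx$alpha, fx$tau), 1e-12)
  expect_error(cv_generalization_error(ys0[1], ds[1], 2, fx$alpha, fx$tau),
               "fold error")
  # pure noise: cv error approaches the noise variance
  sigma_w <- 0.7
  ysn <- with_seed2(3, lapply(ds, function(d) rnorm(d$n_volumes, sd = sigma_w)))
  expect_lt(abs(cv_generalization_error(ysn, ds, 2, 1, 2) - sigma_w^2) /
              sigma_w^2, 0.05)
  # wrong alpha inflates the error in nearly all replicates
  worse <- vapply(1:40, function(s) {
    ys <- fixture_roi_series(ds, fx$h_nov, fx$h_rep, snr = 1, seed = s)
    cv_generalization_error(ys, ds, 2, 3.0, 4) >
      cv_generalization_error(ys, ds, 2, fx$alpha, fx$tau)
  }, logical(1))
  expect_gte(mean(worse), 0.95)
})

test_that("grid search recovers generating parameters and breaks ties low", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(6)
  hits <- vapply(1:10, function(s) {
    ys <- fixture_roi_series(ds, fx$h_nov, fx$h_rep, snr = 3, seed = s)
    gs <- grid_search_basis(ys, ds, L = 2)
    gs$alpha == fx$alpha && gs$tau == fx$tau
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # single grid point passes through
  gs1 <- grid_search_basis(fixture_roi_series(ds, fx$h_nov, fx$h_rep, seed = 1),
                           ds, L = 2, alpha_grid = 2, tau_grid = 3)
  expect_identical(c(gs1$alpha, gs1$tau), c(2, 3))
  # flat zero data: deterministic smallest (tau, alpha)
  ys0 <- lapply(ds, function(d) numeric(d$n_volumes))
  gs0 <- grid_search_basis(ys0, ds, L = 2, alpha_grid = c(0.5, 1),
                           tau_grid = c(0, 2))
  expect_identical(c(gs0$alpha, gs0$tau), c(0.5, 0))
})

test_that("BIC order selection prefers the generating order and penalizes size", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(6)
  picks <- vapply(1:10, function(s) {
    ys <- fixture_roi_series(ds, fx$h_nov, fx$h_rep, snr = 3, seed = s)
    select_model_order(ys, ds, fx$alpha, fx$tau, 1:4)$L
  }, integer(1))
  expect_gte(mean(picks == 2L), 0.9)
  # identical zero data: RSS ties, smaller order wins
  ys0 <- lapply(ds, function(d) numeric(d$n_volumes))
  expect_identical(select_model_order(ys0, ds, 1, 2, 2:4)$L, 2L)
  # pure noise mostly selects the smallest candidate
  noise_picks <- vapply(1:10, function(s) {
    ysn <- with_seed2(100 + s, lapply(ds, function(d) rnorm(d$n_volumes)))
    select_model_order(ysn, ds, 1, 2, 1:4)$L
  }, integer(1))
  expect_gt(mean(noise_picks == 1L), 0.5)
  expect_error(select_model_order(ys0, ds, 1, 2, integer(0)),
               "configuration error")
})

test_that("HRF summaries match closed forms and scale correctly", {
  dt <- 0.1
  t <- seq(0, 24, by = dt)
  s <- 2
  gauss <- exp(-(t - 8)^2 / (2 * s^2))
  sm <- hrf_summaries(gauss, dt)
  expect_equal(sm$fwhm, 2.3548 * s, tolerance = dt)
  expect_equal(sm$peak_latency, 8, tolerance = dt)
  sm2 <- hrf_summaries(2 * gauss, dt)
  expect_equal(sm2$amplitude, 2 * sm$amplitude, tolerance = 1e-12)
  expect_equal(sm2$fwhm, sm$fwhm, tolerance = 1e-12)
  # dominant negative lobe reports a signed amplitude
  smn <- hrf_summaries(-gauss, dt)
  expect_lt(smn$amplitude, 0)
  expect_equal(smn$fwhm, sm$fwhm, tolerance = 1e-12)
  # canonical double-gamma latency against the dense-grid argmax oracle
  h <- make_ground_truth_hrf("double-gamma", dt = dt)
  t_dense <- seq(0, 24, by = 0.001)
  oracle <- dgamma(t_dense, 6, 1) - dgamma(t_dense, 16, 1) / 6
  expect_lt(abs(hrf_summaries(h, dt)$peak_latency -
                  t_dense[which.max(oracle)]), dt)
  expect_error(hrf_summaries(rep(1, 10), dt), "degenerate-curve")
})

test_that("group HRF shape is the first principal direction", {
  h <- make_ground_truth_hrf("double-gamma", dt = 2)
  same <- group_hrf_shape(replicate(5, h, simplify = FALSE))
  expect_equal(same$explained_variance, 1, tolerance = 1e-12)
  expect_gt(cor(same$curve, h), 1 - 1e-10)
  jit <- with_seed2(8, lapply(1:12, function(i) h + rnorm(length(h), sd = 0.02)))
  pj <- group_hrf_shape(jit)
  expect_gte(cor(pj$curve, h), 0.99)
  anti <- group_hrf_shape(list(h, -h))
  expect_gt(max(anti$curve), 0)
  expect_gt(cor(anti$curve, h), 1 - 1e-10)
  expect_error(group_hrf_shape(list(h, h[-1])), "shape error")
})

test_that("the whole estimator is equivariant to output scaling", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(6)
  ys <- fixture_roi_series(ds, fx$h_nov, fx$h_rep, snr = 1, seed = 4)
  e1 <- estimate_hrf_twostep(ys, ys, ds, L = 2,
                             alpha_grid = c(1, 1.5), tau_grid = c(0, 1))
  k <- 3.7
  ysk <- lapply(ys, `*`, k)
  e2 <- estimate_hrf_twostep(ysk, ysk, ds, L = 2,
                             alpha_grid = c(1, 1.5), tau_grid = c(0, 1))
  expect_identical(c(e1$alpha, e1$tau), c(e2$alpha, e2$tau))
  expect_equal(e2$estimates[[1]]$hrf_nov$amplitude,
               k * e1$estimates[[1]]$hrf_nov$amplitude, tolerance = 1e-10)
  expect_equal(e2$estimates[[1]]$hrf_rep$h,
               k * e1$estimates[[1]]$hrf_rep$h, tolerance = 1e-10)
})
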