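test_that("activation GLM recovers ordering and absorbs constants", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(2)
  # noiseless with near-orthogonal regressors: ratio and ordering recovered
  r_nov <- conv_causal2(ds[[1]]$x1, fx$h_nov)
  r_rep <- conv_causal2(ds[[1]]$x2, fx$h_rep)
  zn <- (r_nov - mean(r_nov)) / sd(r_nov)
  zr <- (r_rep - mean(r_rep)) / sd(r_rep)
  y <- 5 + 2 * zn + 1 * zr
  out <- fit_condition_glm(y, ds[[1]], fx$h_nov, fx$h_rep)
  expect_equal(out$pe_nov, 2, tolerance = 1e-6)
  expect_equal(out$pe_rep, 1, tolerance = 1e-6)
  expect_equal(out$contrast, 1, tolerance = 1e-6)
  # adding a constant leaves the contrast untouched
  out2 <- fit_condition_glm(y + 42, ds[[1]], fx$h_nov, fx$h_rep)
  expect_equal(out2$contrast, out$contrast, tolerance = 1e-10)
  # intercept equals mean(y) for centred orthogonal regressors
  y0 <- zn - zr
  expect_equal(fit_condition_glm(y0 + 3, ds[[1]], fx$h_nov,
                                 fx$h_rep)$per_run$intercept,
               mean(y0 + 3), tolerance = 0.05)
  expect_error(fit_condition_glm(y, ds[[1]], numeric(13), fx$h_rep),
               "degenerate-regressor")
})

test_that("equal condition amplitudes give a null contrast distribution", {
  fx <- fixture_span_hrfs()
  d <- fixture_designs(1)[[1]]
  sig <- conv_causal2(d$x1, fx$h_nov) + conv_causal2(d$x2, fx$h_nov)
  cons <- with_seed2(21, vapply(1:200, function(i) {
    y <- sig + rnorm(length(sig), sd = 0.5)
    fit_condition_glm(y, d, fx$h_nov, fx$h_nov)$contrast
  }, numeric(1)))
  expect_lt(abs(mean(cons)), 3 * sd(cons) / sqrt(length(cons)))
})

test_that("per-run parameter estimates are averaged across runs", {
  fx <- fixture_span_hrfs()
  ds <- fixture_designs(3)
  ys <- with_seed2(5, lapply(ds, function(d)
    1.5 * conv_causal2(d$x1, fx$h_nov) + 0.5 * conv_causal2(d$x2, fx$h_rep) +
      rnorm(d$n_volumes, sd = 0.2)))
  out <- fit_condition_glm(ys, ds, fx$h_nov, fx$h_rep)
  expect_identical(nrow(out$per_run), 3L)
  expect_equal(out$contrast, mean(out$per_run$pe_nov - out$per_run$pe_rep),
               tolerance = 1e-12)
  expect_gt(out$contrast, 0)
})

test_that("gPPI design obeys its algebraic contract", {
  fx <- fixture_span_hrfs()
  d <- fixture_designs(1)[[1]]
  seed_ts <- with_seed2(2, conv_causal2(d$x1, fx$h_nov) + rnorm(d$n_volumes, 0.1))
  gp <- build_gppi_design(seed_ts, d, fx$h_nov)
  expect_identical(colnames(gp$X),
                   c("physio", "psych_nov", "psych_rep", "inter_nov", "inter_rep"))
  expect_equal(mean(gp$X[, "physio"]), 0, tolerance = 1e-12)
  # brute-force elementwise product oracle
  oracle_nov <- oracle_rep <- numeric(nrow(gp$X))
  for (i in seq_len(nrow(gp$X))) {
    oracle_nov[i] <- gp$X[i, "psych_nov"] * gp$X[i, "physio"]
    oracle_rep[i] <- gp$X[i, "psych_rep"] * gp$X[i, "physio"]
  }
  expect_lt(max(abs(gp$X[, "inter_nov"] - oracle_nov)), 1e-12)
  expect_lt(max(abs(gp$X[, "inter_rep"] - oracle_rep)), 1e-12)
  # constant seed: physiological and interactions vanish
  gpc <- build_gppi_design(rep(4, d$n_volumes), d, fx$h_nov)
  expect_identical(max(abs(gpc$X[, c("physio", "inter_nov", "inter_rep")])), 0)
  # impulse design: psychological regressor reproduces the group HRF
  imp <- d; imp$x1 <- c(1, numeric(d$n_volumes - 1)); imp$x2 <- numeric(d$n_volumes)
  gpi <- build_gppi_design(seed_ts, imp, fx$h_nov)
  expect_equal(gpi$X[1:13, "psych_nov"], fx$h_nov, tolerance = 1e-12)
})

test_that("gPPI fit recovers exact linear-combination coefficients", {
  fx <- fixture_span_hrfs()
  d <- fixture_designs(1)[[1]]
  seed_ts <- with_seed2(3, conv_causal2(d$x1, fx$h_nov) + rnorm(d$n_volumes, 0.2))
  gp <- build_gppi_design(seed_ts, d, fx$h_nov)
  truth <- c(1.0, 0.3, -0.2, 0.1, 0.8, 0.2)
  y <- drop(cbind(1, gp$X) %*% truth)
  fit <- fit_gppi(y, gp)
  expect_lt(max(abs(fit$pe - truth)), 1e-8)
  expect_equal(fit$fc_contrast, 0.6, tolerance = 1e-8)
})

test_that("planted coupling yields a positive connectivity contrast", {
  fx <- fixture_span_hrfs()
  d <- fixture_designs(1)[[1]]
  gt <- make_ground_truth(fx$h_nov, fx$h_rep, coupling_nov = 0.8,
                          coupling_rep = 0.2, white_sd = 0.3, ar1 = 0.3)
  masks <- make_phantom_masks()
  fcs <- vapply(1:30, function(s) {
    sim <- simulate_bold_run(d, gt, masks, seed = s)
    st <- roi_mean_series(sim$bold, masks$seed)
    tt <- roi_mean_series(sim$bold, masks$target)
    fit_gppi(tt, build_gppi_design(st, d, fx$h_nov))$fc_contrast
  }, numeric(1))
  expect_gte(mean(fcs > 0), 0.95)
  # null coupling: contrast centred at zero
  gt0 <- make_ground_truth(fx$h_nov, fx$h_rep, coupling_nov = 0.4,
                           coupling_rep = 0.4, white_sd = 0.3, ar1 = 0.3)
  fc0 <- vapply(1:30, function(s) {
    sim <- simulate_bold_run(d, gt0, masks, seed = 1000 + s)
    st <- roi_mean_series(sim$bold, masks$seed)
    tt <- roi_mean_series(sim$bold, masks$target)
    fit_gppi(tt, build_gppi_design(st, d, fx$h_nov))$fc_contrast
  }, numeric(1))
  expect_lt(abs(mean(fc0)), 3 * sd(fc0) / sqrt(length(fc0)))
})

test_that("rescaling the seed leaves the gPPI fitted values unchanged", {
  fx <- fixture_span_hrfs()
  d <- fixture_designs(1)[[1]]
  seed_ts <- with_seed2(7, conv_causal2(d$x1, fx$h_nov) + rnorm(d$n_volumes, 0.2))
  y <- with_seed2(8, rnorm(d$n_volumes))
  f1 <- fit_gppi(y, build_gppi_design(seed_ts, d, fx$h_nov))
  f2 <- fit_gppi(y, build_gppi_design(5 * seed_ts, d, fx$h_nov))
  expect_lt(max(abs(f1$fitted - f2$fitted)), 1e-8)
})
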