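test_that("default block schedule reproduces the run arithmetic", {
  ds <- fixture_designs()
  expect_length(ds, 6)
  d <- ds[[1]]
  # 5 + 40 + 25 + 40 + 25 + 40 + 25 + 40 + 5
  expect_identical(d$scheduled_duration_s, 245)
  expect_identical(d$n_volumes, 127)
  # 7 events per novelty block, two novelty blocks per run
  nov <- d$events[d$events$trial_type == "novelty", ]
  expect_identical(nrow(nov), 14L)
  blocks <- split(nov, findInterval(nov$onset, c(0, 70, 1e9)))
  expect_true(all(vapply(blocks, nrow, integer(1)) == 7L))
  # events fit inside the run
  expect_true(all(d$events$onset + d$events$duration <= d$n_volumes * d$tr_seconds))
})

test_that("condition indicators never overlap, under any jitter", {
  for (seed in c(NULL, 1, 2, 3)) {
    ds <- make_task_design(jitter_seed = seed)
    for (d in ds) {
      expect_length(d$x1, d$n_volumes)
      expect_identical(max(d$x1 * d$x2), 0)
    }
  }
})

test_that("degenerate and overflowing schedules are handled", {
  d0 <- make_task_design(2, 1, default_block_spec(block_order = character(0)),
                         n_volumes = 10)[[1]]
  expect_identical(d0$x1, numeric(10))
  expect_identical(d0$x2, numeric(10))
  expect_error(make_task_design(2, 1, n_volumes = 100), "overflows")
  expect_error(
    make_task_design(2, 1, default_block_spec(trial_duration_s = 10)),
    "overflow")
})

test_that("double-gamma truth peaks where the dense-grid oracle says", {
  h <- make_ground_truth_hrf("double-gamma", dt = 0.1)
  t_dense <- seq(0, 24, by = 0.001)
  oracle <- dgamma(t_dense, 6, 1) - dgamma(t_dense, 16, 1) / 6
  expect_lt(abs((which.max(h) - 1) * 0.1 - t_dense[which.max(oracle)]), 0.1)
  expect_identical(h[1], 0)
  expect_error(make_ground_truth_hrf("double-gamma", list(a1 = -1)),
               "parameter error")
})

test_that("laguerre-composed truth is exactly the basis combination", {
  b <- build_basis(2, 12, 1.5, 1, 1, 2)
  cf <- c(0.7, -0.2)
  h <- make_ground_truth_hrf("laguerre-composed",
                             list(basis = b, coef = cf), dt = 2)
  expect_identical(h, drop(b$B %*% cf))
})

test_that("amplitude parameter rescales the curve pointwise", {
  h1 <- make_ground_truth_hrf("double-gamma", list(amplitude = 1), dt = 2)
  h2 <- make_ground_truth_hrf("double-gamma", list(amplitude = 2), dt = 2)
  expect_equal(h2, 2 * h1, tolerance = 1e-12)
})

test_that("ground truth validates its noise model", {
  h <- make_ground_truth_hrf("double-gamma", dt = 2)
  expect_error(make_ground_truth(h, h, white_sd = -1), "parameter error")
  expect_error(make_ground_truth(h, h, ar1 = 1), "parameter error")
})

test_that("noiseless simulation equals the two-condition convolution", {
  ds <- fixture_designs(1)
  h_nov <- make_ground_truth_hrf("double-gamma", list(amplitude = 1), dt = 2)
  h_rep <- make_ground_truth_hrf("double-gamma", list(amplitude = 0.5), dt = 2)
  gt <- make_ground_truth(h_nov, h_rep, beta_nov = 1.2, beta_rep = 0.7,
                          white_sd = 0, ar1 = 0, physio_amp = numeric(0),
                          physio_freq = numeric(0))
  sim <- simulate_bold_run(ds[[1]], gt, seed = 1)
  expected <- 1.2 * conv_causal2(ds[[1]]$x1, h_nov) +
    0.7 * conv_causal2(ds[[1]]$x2, h_rep)
  vox <- roi_mean_series(sim$bold, sim$masks$task_other)
  expect_equal(vox, expected, tolerance = 1e-10)
  # ventricle voxels carry no task signal
  expect_identical(max(abs(roi_mean_series(sim$bold, sim$masks$vent4))), 0)
})

test_that("simulation is a pure function of its seed", {
  ds <- fixture_designs(1)
  h <- make_ground_truth_hrf("double-gamma", dt = 2)
  gt <- make_ground_truth(h, 0.6 * h, coupling_nov = 0.5, white_sd = 0.4)
  a <- simulate_bold_run(ds[[1]], gt, seed = 11)
  b <- simulate_bold_run(ds[[1]], gt, seed = 11)
  expect_identical(a$bold, b$bold)
  expect_identical(a$confounds, b$confounds)
  c2 <- simulate_bold_run(ds[[1]], gt, seed = 12)
  expect_false(identical(a$bold, c2$bold))
})

test_that("residual noise SD matches the generating white SD", {
  ds <- fixture_designs(1)
  h <- make_ground_truth_hrf("double-gamma", dt = 2)
  sigma_w <- 0.4
  gt <- make_ground_truth(h, 0.6 * h, white_sd = sigma_w, ar1 = 0,
                          physio_amp = numeric(0), physio_freq = numeric(0))
  devs <- unlist(lapply(1:50, function(s) {
    sim <- simulate_bold_run(ds[[1]], gt, seed = s)
    resid <- sim$bold - sim$noiseless
    d <- dim(resid)
    m <- matrix(resid, prod(d[1:3]), d[4])
    m[which(sim$masks$brain), ]
  }))
  expect_lt(abs(sd(devs) - sigma_w) / sigma_w, 0.03)
})

test_that("cohort generator honours its degenerate and planted cases", {
  null_coh <- simulate_cohort(20, eq_betas(), random_sd = c(0, 0),
                              resid_sd = 0, seed = 1)
  expect_identical(max(abs(null_coh$outcome)), 0)
  # predA main effect of 1 with everything else silent copies the predictor
  coh <- simulate_cohort(20, eq_betas(beta_a = 1), random_sd = c(0, 0),
                         resid_sd = 0, seed = 2)
  expect_equal(coh$outcome, coh$predA, tolerance = 1e-12)
  expect_error(simulate_cohort(10, random_sd = c(-1, 0)), "parameter error")
})

test_that("every cohort subject has a baseline visit and positive DVR", {
  coh <- simulate_cohort(60, eq_betas(), retention = 0.7, seed = 5)
  base <- tapply(coh$time, coh$subject, min)
  expect_true(all(base == 0))
  expect_true(all(coh$predB > 0))
  expect_identical(coh$amyloid_pos, as.integer(coh$predB > 1.324))
})

test_that("amyloid-positive share converges to the mixture mass", {
  mix <- default_amyloid_mixture()
  p <- amyloid_positive_fraction(mix)
  expect_equal(p, 36 / 128, tolerance = 1e-12)
  coh <- simulate_cohort(4000, eq_betas(), visit_times = 0, seed = 7)
  emp <- mean(coh$predB[!duplicated(coh$subject)] > 1.324)
  # binomial tolerance: 4 SEs at n = 4000
  expect_lt(abs(emp - p), 4 * sqrt(p * (1 - p) / 4000))
})
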