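#' Labelled ROI masks for the simulation phantom
#'
#' Carves a small voxel grid into the regions the pipeline needs: a seed
#' nucleus (standing in for the locus coeruleus), a connectivity target,
#' a 4th-ventricle and lateral-ventricle region (noise only), white matter,
#' and additional task-responsive voxels. Regions are disjoint axis-aligned
#' blocks; everything labelled is inside the analysis ("brain") mask.
#'
#' @param grid_shape Integer length-3 voxel grid dimensions.
#' @return A list of logical 3D arrays: `seed`, `target`, `vent4`,
#'   `latvent`, `wm`, `task_other`, and `brain` (union of all).
#' @export
make_phantom_masks <- function(grid_shape = c(12, 12, 8)) {
  if (any(grid_shape < c(8, 8, 4)))
    stop("mask error: grid_shape must be at least 8 x 8 x 4")
  blank <- function() array(FALSE, dim = grid_shape)
  block <- function(xr, yr, zr) {
    m <- blank(); m[xr, yr, zr] <- TRUE; m
  }
  masks <- list(
    seed       = block(2:3, 2:3, 2:3),
    target     = block(6:8, 2:4, 2:3),
    vent4      = block(2:3, 6:7, 2:3),
    latvent    = block(6:7, 6:7, 2:3),
    wm         = block(2:4, 2:4, 4:min(5, grid_shape[3])),
    task_other = block(6:8, 6:8, 4:min(5, grid_shape[3]))
  )
  if (any(masks$seed & masks$target))
    stop("mask error: seed and target regions overlap")
  masks$brain <- Reduce(`|`, masks)
  masks
}

# AR(1) noise with innovation SD sd and coefficient phi.
ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, sd = sd)
  if (phi == 0) innov else as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Simulate one 4D BOLD run with confounds
#'
#' Generates voxel time-series on a labelled phantom grid following the
#' two-condition linear FIR model: each task voxel carries
#' `beta_nov * (x1 * h_nov) + beta_rep * (x2 * h_rep)` (causal convolutions);
#' target voxels additionally receive condition-scaled copies of the
#' (demeaned, simulated) seed-region mean so planted gPPI coupling is
#' recoverable; ventricle and white-matter voxels carry noise and
#' pseudo-physiology only. Noise per voxel is AR(1) plus linear drift plus
#' sinusoidal pseudo-physiology with random phases. Six synthetic motion
#' parameters (smoothed random walks) and the three ROI-mean series are
#' returned as a confound table. All randomness is a pure function of `seed`.
#'
#' @param design A `task_design` from [make_task_design()].
#' @param ground_truth A [make_ground_truth()] bundle.
#' @param grid_shape Voxel grid passed to [make_phantom_masks()], or a
#'   precomputed mask list.
#' @param seed Integer seed fixing all randomness.
#' @return List with `bold` (4D array x,y,z,t), `confounds` (data frame with
#'   3 ROI-mean + 6 motion columns), `masks`, `design`, `ground_truth`,
#'   `seed`, and `noiseless` (the pure signal array, for oracle tests).
#' @export
simulate_bold_run <- function(design, ground_truth,
                              grid_shape = c(12, 12, 8), seed = 1) {
  masks <- if (is.list(grid_shape) && !is.null(grid_shape$seed)) grid_shape
           else make_phantom_masks(grid_shape)
  if (any(masks$seed & masks$target))
    stop("mask error: seed and target regions overlap")
  gt <- ground_truth
  n <- design$n_volumes
  dims <- dim(masks$brain)
  t_s <- (seq_len(n) - 1L) * design$tr_seconds

  task_sig <- gt$beta_nov * conv_causal(design$x1, gt$hrf_nov) +
    gt$beta_rep * conv_causal(design$x2, gt$hrf_rep)
  # coupling modulators use the seed (novelty) HRF for both conditions,
  # mirroring the gPPI convention of one group-level seed HRF
  psych_nov <- conv_causal(design$x1, gt$hrf_nov)
  psych_rep <- conv_causal(design$x2, gt$hrf_nov)

  with_seed(seed, {
    nz <- gt$noise
    noise_mat <- function(k) {
      # n x k noise draws: AR(1) + drift + random-phase sinusoids
      out <- matrix(0, n, k)
      for (j in seq_len(k)) {
        e <- ar1_noise(n, nz$white_sd, nz$ar1) + nz$drift_per_s * t_s
        if (length(nz$physio_amp))
          for (m in seq_along(nz$physio_amp))
            e <- e + nz$physio_amp[m] *
              sin(2 * pi * nz$physio_freq[m] * t_s + stats::runif(1, 0, 2 * pi))
        out[, j] <- e
      }
      out
    }
    idx_seed <- which(masks$seed)
    idx_target <- which(masks$target)
    idx_other <- which(masks$task_other)
    idx_null <- which(masks$vent4 | masks$latvent | masks$wm)

    flat <- matrix(0, prod(dims), n)          # voxels x time, filled region-wise
    sig_flat <- matrix(0, prod(dims), n)

    flat[idx_seed, ] <- matrix(task_sig, length(idx_seed), n, byrow = TRUE) +
      t(noise_mat(length(idx_seed)))
    sig_flat[idx_seed, ] <- matrix(task_sig, length(idx_seed), n, byrow = TRUE)

    seed_mean <- colMeans(flat[idx_seed, , drop = FALSE])
    seed_centered <- seed_mean - mean(seed_mean)
    coupling_sig <- gt$coupling_nov * psych_nov * seed_centered +
      gt$coupling_rep * psych_rep * seed_centered
    target_sig <- task_sig + coupling_sig
    flat[idx_target, ] <- matrix(target_sig, length(idx_target), n, byrow = TRUE) +
      t(noise_mat(length(idx_target)))
    sig_flat[idx_target, ] <- matrix(target_sig, length(idx_target), n, byrow = TRUE)

    flat[idx_other, ] <- matrix(task_sig, length(idx_other), n, byrow = TRUE) +
      t(noise_mat(length(idx_other)))
    sig_flat[idx_other, ] <- matrix(task_sig, length(idx_other), n, byrow = TRUE)

    flat[idx_null, ] <- t(noise_mat(length(idx_null)))

    motion <- replicate(6, as.numeric(stats::filter(
      cumsum(stats::rnorm(n, sd = 0.02)), rep(1 / 3, 3), sides = 1)))
    motion[is.na(motion)] <- 0

    bold <- array(flat, dim = c(dims, n))
    noiseless <- array(sig_flat, dim = c(dims, n))
    rm_mean <- function(idx) colMeans(flat[idx, , drop = FALSE])
    confounds <- data.frame(
      vent4 = rm_mean(which(masks$vent4)),
      latvent = rm_mean(which(masks$latvent)),
      wm = rm_mean(which(masks$wm)),
      mot1 = motion[, 1], mot2 = motion[, 2], mot3 = motion[, 3],
      mot4 = motion[, 4], mot5 = motion[, 5], mot6 = motion[, 6])
    list(bold = bold, confounds = confounds, masks = masks, design = design,
         ground_truth = gt, seed = seed, noiseless = noiseless)
  })
}

#' Mean time-series over a mask
#' @param bold 4D array.
#' @param mask Logical 3D array.
#' @return Numeric series of length `dim(bold)[4]`.
#' @export
roi_mean_series <- function(bold, mask) {
  if (!any(mask)) stop("mask error: mask selects no voxels")
  d <- dim(bold)
  flat <- matrix(bold, prod(d[1:3]), d[4])
  colMeans(flat[which(mask), , drop = FALSE])
}
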