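#' Assemble the 30-column nuisance confound set
#'
#' Expands three ROI-mean series (4th ventricle, lateral ventricles, white
#' matter) and six motion parameters into the full nuisance set: the 9 raw
#' series, backward-difference derivatives of the 6 motion parameters
#' (leading element 0), and the squares of all 15 preceding series —
#' 3 + 6 + 6 + 15 = 30 columns.
#'
#' @param roi_means Data frame or matrix with columns `vent4`, `latvent`,
#'   `wm` (in that order if unnamed).
#' @param motion6 Data frame or matrix of the 6 motion parameter series.
#' @return A 30-column data frame of class `confound_set`.
#' @export
build_confounds <- function(roi_means, motion6) {
  roi_means <- as.data.frame(roi_means)
  motion6 <- as.data.frame(motion6)
  if (ncol(roi_means) != 3)
    stop("input error: need exactly the 3 ROI-mean series (4th ventricle, lateral ventricles, white matter)")
  if (ncol(motion6) != 6) stop("input error: need exactly 6 motion series")
  if (nrow(roi_means) != nrow(motion6)) stop("input error: series lengths differ")
  names(roi_means) <- c("vent4", "latvent", "wm")
  names(motion6) <- paste0("mot", 1:6)
  deriv <- as.data.frame(lapply(motion6, function(x) c(0, diff(x))))
  names(deriv) <- paste0("mot", 1:6, "_deriv")
  base <- cbind(roi_means, motion6, deriv)
  squares <- as.data.frame(lapply(base, function(x) x^2))
  names(squares) <- paste0(names(base), "_sq")
  out <- cbind(base, squares)
  stopifnot(ncol(out) == 30)
  class(out) <- c("confound_set", "data.frame")
  out
}

#' Remove nuisance structure by voxel-wise linear regression
#'
#' Regresses every voxel series on an intercept plus the confound columns by
#' OLS and returns the residuals (shape-preserving for matrix or 4D input).
#'
#' @param Y Time-by-voxel matrix, a single series, or a 4D array (x,y,z,t).
#' @param confounds A [build_confounds()] table (or any full-rank regressor
#'   data frame/matrix).
#' @return Residuals in the shape of `Y`.
#' @export
nuisance_regress <- function(Y, confounds) {
  X <- cbind(intercept = 1, as.matrix(confounds))
  qrd <- qr(X)
  if (qrd$rank < ncol(X)) {
    dep <- colnames(X)[qrd$pivot[(qrd$rank + 1):ncol(X)]]
    stop("rank deficiency in confound matrix; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  reshape4d <- is.array(Y) && length(dim(Y)) == 4
  if (reshape4d) {
    d <- dim(Y)
    Ym <- t(matrix(Y, prod(d[1:3]), d[4]))
  } else Ym <- as.matrix(Y)
  if (nrow(Ym) != nrow(X)) stop("time dimension of Y must match the confounds")
  res <- qr.resid(qrd, Ym)
  if (reshape4d) array(t(res), dim = d)
  else if (is.null(dim(Y))) drop(res) else res
}

#' DVARS computation and volume scrubbing
#'
#' DVARS at volume `t` (t = 2..N) is the root mean square over in-mask
#' voxels of the backward temporal difference. Volumes whose DVARS exceeds
#' the threshold are flagged for removal (together with their design rows,
#' which is the caller's responsibility). The default threshold is the
#' robust upper fence of the run's own DVARS distribution,
#' `Q3 + 1.5 * IQR`.
#'
#' @param Y 4D array or time-by-voxel matrix.
#' @param threshold Absolute DVARS threshold; `NULL` for the robust default.
#' @param mask Optional logical 3D array restricting the voxel set.
#' @return List: `dvars` (length N-1), `threshold`, `removed` (volume
#'   indices), `retained`.
#' @export
dvars_scrub <- function(Y, threshold = NULL, mask = NULL) {
  if (is.array(Y) && length(dim(Y)) == 4) {
    d <- dim(Y)
    Ym <- t(matrix(Y, prod(d[1:3]), d[4]))
    if (!is.null(mask)) {
      if (!any(mask)) stop("mask error: empty mask")
      Ym <- Ym[, which(mask), drop = FALSE]
    }
  } else {
    Ym <- as.matrix(Y)
    if (!is.null(mask)) {
      if (!any(mask)) stop("mask error: empty mask")
      Ym <- Ym[, which(mask), drop = FALSE]
    }
  }
  n <- nrow(Ym)
  if (n < 2) stop("need >= 2 volumes")
  dvars <- sqrt(rowMeans((Ym[-1, , drop = FALSE] - Ym[-n, , drop = FALSE])^2))
  if (is.null(threshold)) {
    q <- stats::quantile(dvars, c(0.25, 0.75), names = FALSE)
    threshold <- q[2] + 1.5 * (q[2] - q[1])
  }
  removed <- which(dvars > threshold) + 1L     # flag the later volume
  list(dvars = dvars, threshold = threshold,
       removed = removed, retained = setdiff(seq_len(n), removed))
}

# 1D Gaussian smoothing matrix with edge renormalization so row sums are 1
# (constant signals pass through unchanged).
gauss_smooth_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- (-r):r
  w <- exp(-k^2 / (2 * sigma_vox^2))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + k
    ok <- j >= 1 & j <= n
    A[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  A
}

#' Anisotropic (ellipsoid) Gaussian smoothing
#'
#' Separable axis-aligned Gaussian smoothing with a different FWHM per axis,
#' designed to enhance detection of elongated structures (e.g. brainstem
#' nuclei) by smoothing more along their long axis. The kernel is truncated
#' at 4 SD and renormalized (including at volume edges) so it has unit mass
#' and preserves constant images exactly.
#'
#' @param volume 3D or 4D array.
#' @param fwhm_xyz_mm Length-3 positive FWHMs in mm.
#' @param voxel_size_mm Length-3 voxel dimensions in mm.
#' @return Smoothed array, same shape.
#' @export
ellipsoid_smooth <- function(volume, fwhm_xyz_mm, voxel_size_mm = c(1, 1, 1)) {
  if (length(fwhm_xyz_mm) != 3 || any(fwhm_xyz_mm <= 0))
    stop("need three positive FWHMs")
  sigma_vox <- fwhm_xyz_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  if (any(fwhm_xyz_mm / voxel_size_mm < 0.1))
    stop("degenerate-kernel error: FWHM below 0.1 voxel")
  d <- dim(volume)
  is4d <- length(d) == 4
  dims <- if (is4d) d[1:3] else d
  A <- lapply(1:3, function(ax) gauss_smooth_matrix(dims[ax], sigma_vox[ax]))
  smooth3d <- function(v) {
    # axis 1
    m <- matrix(v, dims[1], dims[2] * dims[3])
    v <- array(A[[1]] %*% m, dims)
    # axis 2
    p <- aperm(v, c(2, 1, 3))
    m <- matrix(p, dims[2], dims[1] * dims[3])
    v <- aperm(array(A[[2]] %*% m, dims[c(2, 1, 3)]), c(2, 1, 3))
    # axis 3
    p <- aperm(v, c(3, 1, 2))
    m <- matrix(p, dims[3], dims[1] * dims[2])
    aperm(array(A[[3]] %*% m, dims[c(3, 1, 2)]), c(2, 3, 1))
  }
  if (!is4d) return(smooth3d(volume))
  out <- array(0, d)
  for (t in seq_len(d[4])) out[, , , t] <- smooth3d(volume[, , , t])
  out
}

#' Seed-to-ventricle correlation diagnostic
#'
#' Pearson correlation between the seed-region and 4th-ventricle mean
#' series; a high correlation indicates partial-volume contamination of the
#' seed by CSF signal.
#'
#' @param seed_ts,ventricle_ts Equal-length numeric series.
#' @return Pearson r in \[-1, 1\].
#' @export
seed_ventricle_correlation <- function(seed_ts, ventricle_ts) {
  if (length(seed_ts) != length(ventricle_ts)) stop("series lengths differ")
  if (stats::sd(seed_ts) == 0 || stats::sd(ventricle_ts) == 0)
    stop("degenerate-series error: zero variance input")
  stats::cor(seed_ts, ventricle_ts)
}
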