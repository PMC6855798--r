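#' Framewise displacement from motion parameters
#'
#' Power-style FD: the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations (radians) converted to arc
#' length on a 50 mm sphere.  The first frame is 0 by convention.
#'
#' @param motion A `time x 6` matrix or data frame: three translations in
#'   mm followed by three rotations.  Set `rotation_unit = "degrees"` for
#'   motion files whose rotations are in degrees.
#' @param rotation_unit `"radians"` (default) or `"degrees"`.
#' @param radius_mm Rotation-to-arc-length radius (50 mm convention).
#' @return Numeric FD series (mm), one value per frame.
#' @examples
#' m <- matrix(0, 10, 6); m[5, 1] <- 0.3
#' compute_fd(m)
#' @export
compute_fd <- function(motion, rotation_unit = c("radians", "degrees"),
                       radius_mm = 50) {
  rotation_unit <- match.arg(rotation_unit)
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) abort("`motion` must have 6 columns.")
  if (nrow(motion) < 2L) abort("`motion` needs at least 2 frames.")
  rot <- motion[, 4:6, drop = FALSE]
  if (rotation_unit == "degrees") rot <- rot * pi / 180
  d_trans <- abs(diff(motion[, 1:3, drop = FALSE]))
  d_rot <- abs(diff(rot)) * radius_mm
  c(0, rowSums(d_trans) + rowSums(d_rot))
}

#' Read a plain-text motion-parameter file
#'
#' Whitespace-delimited, one row per frame, three translations (mm) then
#' three rotations.
#'
#' @param path File path.
#' @return A numeric `time x 6` matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(read.table(path))
  if (ncol(m) != 6L) abort(sprintf("'%s' does not have 6 columns.", path))
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_roll", "rot_pitch", "rot_yaw")
  m
}

#' Motion-based scan exclusion
#'
#' A scan is excluded when the fraction of frames with FD above
#' `threshold_mm` strictly exceeds `max_fraction` (retained scans in the
#' study design all had under 5% of frames censored).
#'
#' @param fd_series FD values from [compute_fd()].
#' @param threshold_mm FD censoring threshold (default 0.3 mm).
#' @param max_fraction Maximum tolerated censored fraction (default 0.05).
#' @return One-row tibble: `n_frames`, `n_censored`, `censored_fraction`,
#'   `exclude`.
#' @export
qc_exclude <- function(fd_series, threshold_mm = 0.3, max_fraction = 0.05) {
  if (!length(fd_series)) abort("`fd_series` is empty.")
  n_cens <- sum(fd_series > threshold_mm)
  frac <- n_cens / length(fd_series)
  tibble(n_frames = length(fd_series), n_censored = n_cens,
         censored_fraction = frac, exclude = frac > max_fraction)
}

#' Regress nuisance time series out of a scan
#'
#' Per-voxel least-squares residuals after projecting onto an intercept
#' plus the supplied regressors (e.g. the six motion parameters).
#' Rank-deficient regressor sets are handled by pivoting with a warning.
#'
#' @param series A [volume_series()].
#' @param regressors `time x k` matrix/data frame, rows matching frames.
#' @return A [volume_series()] of residuals (orthogonal to the
#'   regressors).
#' @export
regress_nuisance <- function(series, regressors) {
  stopifnot(is_volume_series(series))
  X <- cbind(intercept = 1, as.matrix(regressors))
  if (nrow(X) != n_frames(series)) {
    abort("regressor rows do not match the number of frames.")
  }
  Y <- as_time_by_voxel(series)
  fit <- lm.fit(X, Y)
  if (fit$rank < ncol(X)) {
    warn(sprintf("nuisance regressors are rank deficient (rank %d of %d); pivoted fit used.",
                 fit$rank, ncol(X)))
  }
  time_by_voxel_to_series(fit$residuals, series)
}

#' Bandpass filter a scan in the frequency domain
#'
#' Discrete-Fourier projection: frequency bins with `|f|` in
#' `[low_hz, high_hz]` are retained, all others (including DC) are
#' zeroed, so the output has mean ~0 and the operation is idempotent.
#'
#' @param series A [volume_series()].
#' @param low_hz,high_hz Passband edges; must satisfy
#'   `0 <= low_hz < high_hz < 1 / (2 * TR)`.
#' @return Filtered [volume_series()].
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(is_volume_series(series))
  nyquist <- 1 / (2 * series$tr_s)
  if (low_hz < 0 || high_hz <= low_hz || high_hz >= nyquist) {
    abort(sprintf("band [%.4g, %.4g] Hz must lie inside (0, Nyquist = %.4g) Hz.",
                  low_hz, high_hz, nyquist))
  }
  Y <- as_time_by_voxel(series)
  n <- nrow(Y)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) / (n * series$tr_s)
  keep <- freq >= low_hz & freq <= high_hz
  F <- mvfft(Y)
  F[!keep, ] <- 0
  out <- Re(mvfft(F, inverse = TRUE)) / n
  time_by_voxel_to_series(out, series)
}

# 1D Gaussian kernel for a sigma given in voxels, truncated at 4 sigma.
gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(-r:r, sd = sigma_vox)
  k / sum(k)
}

# Convolve a 3D array along one axis with a short symmetric kernel,
# zero-padded at the edges.
conv_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  A <- aperm(arr, perm)
  M <- matrix(A, d[axis])
  out <- matrix(0, nrow(M), ncol(M))
  r <- (length(kernel) - 1L) / 2L
  n <- nrow(M)
  for (o in -r:r) {
    lo <- max(1L, 1L - o)
    hi <- min(n, n - o)
    if (lo > hi) next  # kernel wider than the axis
    dst <- lo:hi
    out[dst, ] <- out[dst, ] + kernel[o + r + 1L] * M[dst + o, , drop = FALSE]
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` converted to voxels per axis
#' (anisotropic voxels are handled per-axis).  An optional mask zeroes
#' out-of-mask voxels after smoothing.
#'
#' @param series A [volume_series()].
#' @param fwhm_mm Kernel full-width at half-maximum in mm (default 4).
#' @param mask Optional logical 3D array.
#' @return Smoothed [volume_series()].
#' @export
smooth_gaussian <- function(series, fwhm_mm = 4, mask = NULL) {
  stopifnot(is_volume_series(series))
  assert_scalar_number(fwhm_mm, "fwhm_mm", positive = TRUE)
  if (any(series$voxel_size_mm <= 0)) abort("voxel sizes must be positive.")
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / series$voxel_size_mm
  kernels <- lapply(sigma_vox, gaussian_kernel_1d)
  d <- dim(series$data)
  out <- series$data
  for (t in seq_len(d[4])) {
    frame <- out[, , , t]
    for (ax in 1:3) frame <- conv_axis(frame, kernels[[ax]], ax)
    if (!is.null(mask)) frame <- frame * mask
    out[, , , t] <- frame
  }
  volume_series(out, series$voxel_size_mm, series$tr_s, series$origin_mm)
}

#' Temporal signal-to-noise ratio
#'
#' Mean over in-mask voxels of (temporal mean / temporal SD).  Voxels
#' with zero temporal SD are excluded with a warning.
#'
#' @param series A [volume_series()].
#' @param mask Optional logical 3D array (default: whole grid).
#' @return Scalar tSNR.
#' @export
compute_tsnr <- function(series, mask = NULL) {
  stopifnot(is_volume_series(series))
  Y <- as_time_by_voxel(series)
  keep <- if (is.null(mask)) rep(TRUE, ncol(Y)) else as.logical(mask)
  if (!any(keep)) abort("mask is empty.")
  Y <- Y[, keep, drop = FALSE]
  mu <- colMeans(Y)
  sdv <- apply(Y, 2, sd)
  bad <- sdv == 0
  if (all(bad)) abort("all in-mask voxels have zero temporal SD.")
  if (any(bad)) {
    warn(sprintf("%d zero-SD voxel(s) excluded from tSNR.", sum(bad)))
  }
  mean(mu[!bad] / sdv[!bad])
}

#' Intersect subject masks into a group mask
#'
#' @param masks List of logical/binary 3D arrays of identical shape.
#' @return Logical 3D array: voxels present in every mask.
#' @export
group_mask <- function(masks) {
  if (!length(masks)) abort("`masks` is empty.")
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("all masks must have identical shapes.")
  }
  Reduce(`&`, lapply(masks, function(m) array(m != 0, dim(m))))
}

#' Run the per-scan preprocessing chain
#'
#' Fixed order: nuisance regression of the motion parameters, bandpass,
#' spatial smoothing, masking.  (Frame trimming happens at load in
#' [read_volume_series()]; despiking/slice-time correction are assumed
#' upstream.)  tSNR is computed after motion regression and before the
#' bandpass, since the bandpass removes the mean and would leave the
#' ratio undefined.  Frames with FD above threshold are flagged for QC
#' only; they are not removed from the retained series.
#'
#' @param series A [volume_series()].
#' @param motion `time x 6` motion matrix for the same scan.
#' @param mask Optional logical 3D array.
#' @param fd_threshold_mm,max_censored_fraction QC rule parameters.
#' @param band_low_hz,band_high_hz,fwhm_mm Filter/smoothing parameters.
#' @return List with `series` (preprocessed) and `qc` (one-row tibble
#'   with FD summary, censoring decision and tSNR).
#' @export
preprocess_scan <- function(series, motion, mask = NULL,
                            fd_threshold_mm = 0.3, max_censored_fraction = 0.05,
                            band_low_hz = 0.01, band_high_hz = 0.1,
                            fwhm_mm = 4) {
  fd <- compute_fd(motion)
  qc <- qc_exclude(fd, fd_threshold_mm, max_censored_fraction)
  clean <- regress_nuisance(series, motion)
  # signal = raw temporal mean, noise = post-regression residual SD; the
  # regression itself removes the mean, so the raw mean is restored here
  baseline <- array(rep(apply(series$data, 1:3, mean), n_frames(series)),
                    dim(series$data))
  with_mean <- volume_series(clean$data + baseline, series$voxel_size_mm,
                             series$tr_s, series$origin_mm)
  qc$tsnr <- compute_tsnr(with_mean, mask)
  qc$mean_fd <- mean(fd)
  clean <- bandpass(clean, band_low_hz, band_high_hz)
  clean <- smooth_gaussian(clean, fwhm_mm, mask)
  list(series = clean, qc = qc)
}
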