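#' A 4D voxel time series
#'
#' Light container for one scan's functional data: a 4D array indexed
#' `[x, y, z, t]` plus the voxel size (mm), repetition time (s) and the mm
#' coordinate of the first voxel's centre.  Coordinates are in the
#' dataset's common space; voxel indices are 1-based internally.
#'
#' @param data 4D numeric array `[x, y, z, t]` with at least 2 frames and
#'   no non-finite values.
#' @param voxel_size_mm Numeric length-3, voxel edge lengths in mm.
#' @param tr_s Repetition time in seconds.
#' @param origin_mm Numeric length-3, mm coordinate of voxel `(1, 1, 1)`.
#' @return A `volume_series` object.
#' @examples
#' vs <- volume_series(array(rnorm(4 * 4 * 4 * 10), c(4, 4, 4, 10)))
#' dim(vs$data)
#' @export
volume_series <- function(data, voxel_size_mm = c(2, 2, 2), tr_s = 2,
                          origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    abort("`data` must be a 4D array [x, y, z, t].")
  }
  if (dim(data)[4] < 2L) abort("`data` must have at least 2 frames.")
  if (!all(is.finite(data))) abort("`data` contains non-finite values.")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (any(voxel_size_mm <= 0)) abort("`voxel_size_mm` must be positive.")
  assert_scalar_number(tr_s, "tr_s", positive = TRUE)
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         tr_s = tr_s, origin_mm = as.numeric(origin_mm)),
    class = "volume_series"
  )
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels, %d frames, voxel %s mm, TR %.3g s\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size_mm, 3), collapse = "x"), x$tr_s))
  invisible(x)
}

is_volume_series <- function(x) inherits(x, "volume_series")

vol_dims <- function(x) dim(x$data)[1:3]

n_frames <- function(x) dim(x$data)[4]

# time x voxel matrix of the full grid (column order = R array order)
as_time_by_voxel <- function(x) {
  d <- dim(x$data)
  t(matrix(x$data, prod(d[1:3]), d[4]))
}

time_by_voxel_to_series <- function(mat, template) {
  d <- dim(template$data)
  volume_series(array(t(mat), d), template$voxel_size_mm, template$tr_s,
                template$origin_mm)
}

# mm coordinates of voxel centres for 1-based index rows of `idx` (n x 3)
voxel_coords_mm <- function(idx, voxel_size_mm, origin_mm = c(0, 0, 0)) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, voxel_size_mm, `*`), 2, origin_mm, `+`)
}

#' Read and write functional volumes as NIfTI-1
#'
#' `read_volume_series()` loads a 4D NIfTI file, drops the initial frames
#' (5 by default, discarded to avoid intensity-normalisation artifact) and
#' records voxel size and TR from the header.  `write_volume_series()`
#' writes a [volume_series()] back to NIfTI-1 with voxel size and TR in
#' `pixdim`.
#'
#' @param path File path.
#' @param drop_initial Number of leading frames to discard on read.
#' @param tr_s Repetition time override; taken from the header when `NULL`.
#' @return `read_volume_series()` returns a [volume_series()];
#'   `write_volume_series()` returns `path` invisibly.
#' @export
read_volume_series <- function(path, drop_initial = 5, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) abort("expected a 4D NIfTI volume.")
  pd <- RNifti::pixdim(img)
  if (drop_initial > 0) {
    if (dim(arr)[4] - drop_initial < 2) {
      abort("fewer than 2 frames remain after dropping initial volumes.")
    }
    arr <- arr[, , , -seq_len(drop_initial), drop = FALSE]
  }
  if (!all(is.finite(arr))) abort(sprintf("non-finite values in '%s'.", path))
  volume_series(arr, voxel_size_mm = pd[1:3],
                tr_s = tr_s %||% if (length(pd) >= 4 && pd[4] > 0) pd[4] else 2)
}

#' @rdname read_volume_series
#' @param series A [volume_series()].
#' @export
write_volume_series <- function(series, path) {
  stopifnot(is_volume_series(series))
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size_mm, series$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read and write 3D volumes (masks, label atlases, statistic maps)
#'
#' @param path File path.
#' @param logical Return a logical array (non-zero = `TRUE`)?
#' @return `read_volume()` returns a 3D array; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, logical = FALSE) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) abort("expected a 3D NIfTI volume.")
  if (logical) arr <- arr != 0
  arr
}

#' @rdname read_volume
#' @param volume 3D array.
#' @param voxel_size_mm Voxel size to record in the header.
#' @export
write_volume <- function(volume, path, voxel_size_mm = c(2, 2, 2)) {
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
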