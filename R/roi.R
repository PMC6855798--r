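#' Voxels inside a spherical ROI
#'
#' Returns every voxel whose centre lies within `radius_mm` (inclusive)
#' of `center_mm`, optionally intersected with an analysis mask.  Voxel
#' centres are `origin_mm + (index - 1) * voxel_size_mm`.
#'
#' @param center_mm Numeric length-3 sphere centre (mm); must fall inside
#'   the volume bounds.
#' @param radius_mm Sphere radius (mm).
#' @param dims Integer length-3 grid dimensions.
#' @param voxel_size_mm Voxel size (mm).
#' @param origin_mm mm coordinate of voxel `(1, 1, 1)`.
#' @param mask Optional logical 3D array.
#' @param region Region name used in error messages.
#' @return Integer `n x 3` matrix of 1-based voxel indices.
#' @examples
#' nrow(sphere_voxels(c(16, 16, 16), 6, c(16, 16, 16), c(2, 2, 2)))  # 123
#' @export
sphere_voxels <- function(center_mm, radius_mm, dims, voxel_size_mm = c(2, 2, 2),
                          origin_mm = c(0, 0, 0), mask = NULL,
                          region = "region") {
  stopifnot(length(center_mm) == 3, length(dims) == 3)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  lo <- origin_mm - voxel_size_mm / 2
  hi <- origin_mm + (dims - 1) * voxel_size_mm + voxel_size_mm / 2
  if (any(center_mm < lo) || any(center_mm > hi)) {
    abort(sprintf("center of '%s' lies outside the volume bounds.", region))
  }
  rng <- lapply(1:3, function(a) {
    i <- seq_len(dims[a])
    i[abs(origin_mm[a] + (i - 1) * voxel_size_mm[a] - center_mm[a]) <=
        radius_mm + 1e-9]
  })
  if (any(lengths(rng) == 0)) cand <- matrix(integer(), 0, 3)
  else cand <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  if (nrow(cand)) {
    centers <- voxel_coords_mm(cand, voxel_size_mm, origin_mm)
    d2 <- rowSums(sweep(centers, 2, center_mm)^2)
    cand <- cand[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    # fall back to the single nearest voxel centre for tiny radii
    nearest <- pmin(pmax(round((center_mm - origin_mm) / voxel_size_mm) + 1, 1), dims)
    cand <- matrix(as.integer(nearest), 1)
  }
  if (!is.null(mask)) {
    keep <- mask[cand]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) {
      abort(sprintf("sphere for '%s' lies entirely outside the mask.", region))
    }
  }
  storage.mode(cand) <- "integer"
  dimnames(cand) <- list(NULL, c("x", "y", "z"))
  cand
}

#' Spatially averaged ROI time series
#'
#' @param series A [volume_series()] or 4D array.
#' @param voxels Integer `n x 3` voxel-index matrix (from
#'   [sphere_voxels()]).
#' @return Numeric time vector (unweighted mean over the voxels).
#' @export
extract_mean_timeseries <- function(series, voxels) {
  arr <- if (is_volume_series(series)) series$data else series
  voxels <- matrix(as.integer(voxels), ncol = 3)
  if (!nrow(voxels)) abort("`voxels` is empty.")
  d <- dim(arr)
  lin <- voxels[, 1] + (voxels[, 2] - 1L) * d[1] + (voxels[, 3] - 1L) * d[1] * d[2]
  M <- matrix(arr, prod(d[1:3]), d[4])
  colMeans(M[lin, , drop = FALSE])
}

#' Extract all atlas ROI series from one scan
#'
#' @param series A [volume_series()].
#' @param atlas Atlas tibble (see [read_atlas()]).
#' @param mask Optional logical 3D array.
#' @return `region x time` matrix with region names as rownames.
#' @export
extract_roi_matrix <- function(series, atlas, mask = NULL) {
  stopifnot(is_volume_series(series))
  atlas <- validate_atlas(atlas)
  d <- vol_dims(series)
  out <- matrix(NA_real_, nrow(atlas), n_frames(series),
                dimnames = list(atlas$name, NULL))
  for (i in seq_len(nrow(atlas))) {
    vox <- sphere_voxels(c(atlas$x_mm[i], atlas$y_mm[i], atlas$z_mm[i]),
                         atlas$radius_mm[i], d, series$voxel_size_mm,
                         series$origin_mm, mask, atlas$name[i])
    out[i, ] <- extract_mean_timeseries(series, vox)
  }
  out
}

#' Fisher-z connectivity matrix for one scan
#'
#' Pairwise Pearson correlations between region time series, clamped to
#' `|r| <= 1 - 1e-7` and arctanh-transformed.  The diagonal is `NA` and
#' excluded from all summaries.
#'
#' @param region_series `region x time` matrix (>= 3 frames, every
#'   region with positive SD).
#' @return Symmetric `conn_matrix` (region x region Fisher z, `NA`
#'   diagonal).
#' @export
connectivity_matrix <- function(region_series) {
  region_series <- as.matrix(region_series)
  if (ncol(region_series) < 3) abort("need >= 3 timepoints.")
  sds <- apply(region_series, 1, sd)
  if (any(sds == 0)) {
    bad <- rownames(region_series)[sds == 0] %||% which(sds == 0)
    abort(paste0("zero-variance region(s): ", paste(bad, collapse = ", ")))
  }
  z <- atanh(clamp_r(cor(t(region_series))))
  diag(z) <- NA_real_
  class(z) <- c("conn_matrix", class(z))
  z
}

members_in <- function(matrix, members) {
  nms <- rownames(matrix) %||% seq_len(nrow(matrix))
  if (is.character(members)) {
    idx <- match(members, nms)
    if (anyNA(idx)) abort("unknown region name(s) in `members`.")
    idx
  } else as.integer(members)
}

#' Network interconnectivity
#'
#' Mean Fisher-z over all distinct pairs of the member regions (the
#' off-diagonal upper triangle of the member submatrix).
#'
#' @param matrix A [connectivity_matrix()].
#' @param members Region names or indices (>= 2).
#' @return Scalar mean z.
#' @export
network_interconnectivity <- function(matrix, members) {
  idx <- members_in(matrix, members)
  if (length(idx) < 2) abort("need >= 2 member regions.")
  sub <- matrix[idx, idx]
  mean(sub[upper.tri(sub)])
}

#' Region-to-network mean connectivity
#'
#' Mean Fisher-z between one region and the other members of its network.
#'
#' @inheritParams network_interconnectivity
#' @param region Region name or index; must be one of `members`.
#' @return Scalar mean z.
#' @export
region_mean_connectivity <- function(matrix, region, members) {
  idx <- members_in(matrix, members)
  r <- members_in(matrix, region)
  if (!r %in% idx) abort("`region` must be one of `members`.")
  if (length(idx) < 2) abort("need >= 2 member regions.")
  mean(matrix[r, setdiff(idx, r)])
}

#' Long-format network connectivity table
#'
#' One row per scan per network: the contract consumed by [fit_lme()].
#'
#' @param matrices Named list of [connectivity_matrix()] keyed by
#'   `scan_id`.
#' @param scans Scan tibble with `scan_id` and a `tsnr` column.
#' @param atlas Atlas tibble.
#' @param networks Networks to summarise.
#' @return Tibble with `subject_id`, `group`, `condition`, `task`,
#'   `order`, `tsnr`, `network`, `value`.
#' @export
network_connectivity_table <- function(matrices, scans, atlas,
                                       networks = c("PMN", "ATN")) {
  atlas <- validate_atlas(atlas)
  purrr::map(networks, function(net) {
    members <- atlas$name[atlas$network == net]
    scans |>
      mutate(network = net,
             value = map_dbl(.data$scan_id, function(id) {
               network_interconnectivity(matrices[[id]], members)
             }))
  }) |>
    list_rbind() |>
    select(any_of(c("subject_id", "group", "condition", "task", "order",
                    "tsnr", "network", "value")))
}

#' Long-format edge connectivity table
#'
#' One row per scan per within-network region pair: the input for
#' [edge_interaction_tests()].
#'
#' @inheritParams network_connectivity_table
#' @return Tibble with the scan factors plus `network`, `region_a`,
#'   `region_b`, `value`.
#' @export
edge_connectivity_table <- function(matrices, scans, atlas,
                                    networks = c("PMN", "ATN")) {
  atlas <- validate_atlas(atlas)
  pairs <- purrr::map(networks, function(net) {
    members <- atlas$name[atlas$network == net]
    if (length(members) < 2) return(NULL)
    cmb <- utils::combn(members, 2)
    tibble(network = net, region_a = cmb[1, ], region_b = cmb[2, ])
  }) |> list_rbind()
  expand_grid(scans, pairs) |>
    mutate(value = unlist(purrr::pmap(list(.data$scan_id, .data$region_a, .data$region_b),
                                      function(id, a, b) matrices[[id]][a, b]))) |>
    select(any_of(c("subject_id", "group", "condition", "task", "order",
                    "tsnr", "network", "region_a", "region_b", "value")))
}

#' Select a stimulation-target voxel from a connectivity map
#'
#' Returns the in-mask voxel with the maximal map value; ties are broken
#' by smaller Euclidean distance to `anchor_mm`, then by lexicographic
#' voxel index.  Used both for picking the peak-connectivity parietal
#' target and, with a small spherical candidate mask (default search
#' radius 8 mm around an anatomical coordinate), for hippocampal seed
#' selection.
#'
#' @param map 3D statistic/connectivity array.
#' @param mask Logical 3D candidate mask (nonempty).
#' @param anchor_mm Anchor coordinate for tie-breaking and the reported
#'   distance.
#' @param voxel_size_mm,origin_mm Grid geometry.
#' @return One-row tibble: voxel indices, mm coordinates, `value`,
#'   `distance_mm` to the anchor.
#' @export
select_stimulation_target <- function(map, mask, anchor_mm,
                                      voxel_size_mm = c(2, 2, 2),
                                      origin_mm = c(0, 0, 0)) {
  idx <- which(mask != 0)
  if (!length(idx)) abort("candidate mask is empty.")
  vals <- map[idx]
  top <- idx[vals == max(vals)]
  coords <- arrayInd(top, dim(map))
  mm <- voxel_coords_mm(coords, voxel_size_mm, origin_mm)
  dist <- sqrt(rowSums(sweep(mm, 2, anchor_mm)^2))
  pick <- order(dist, top)[1]
  tibble(x = coords[pick, 1], y = coords[pick, 2], z = coords[pick, 3],
         x_mm = mm[pick, 1], y_mm = mm[pick, 2], z_mm = mm[pick, 3],
         value = max(vals), distance_mm = dist[pick])
}
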