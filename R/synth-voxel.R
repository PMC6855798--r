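#' Block community map for simulated voxel grids
#'
#' Places `n_communities` cubic blocks of side `block_side` voxels at
#' evenly spaced anchors inside the grid; remaining voxels are background
#' (label 0).  Communities alternate between `PMN` and `ATN` network
#' identities (stored in the `"networks"` attribute), so planted effects
#' can be restricted to one network's communities.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @param n_communities Number of blocks (default 8, one per octant for
#'   cubic grids).
#' @param block_side Block edge length in voxels.
#' @return Integer 3D label array with attribute `networks` (named
#'   character vector, one entry per community label).
#' @examples
#' cm <- block_community_map(c(16, 16, 16))
#' table(cm)
#' @export
block_community_map <- function(grid_shape, n_communities = 8,
                                block_side = 4) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= block_side))
  # anchors on a 2x2x2 octant lattice, recycled if more communities asked
  oct <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  if (n_communities > nrow(oct)) {
    abort("`n_communities` must be <= 8 for the block layout.")
  }
  labels <- array(0L, grid_shape)
  starts <- pmax(1L, floor(grid_shape / 4) - floor(block_side / 2) + 1L)
  for (k in seq_len(n_communities)) {
    lo <- starts + oct[k, ] * floor(grid_shape / 2)
    hi <- pmin(lo + block_side - 1L, grid_shape)
    labels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- k
  }
  attr(labels, "networks") <- setNames(
    rep(c("PMN", "ATN"), length.out = n_communities),
    as.character(seq_len(n_communities)))
  labels
}

#' Simulate voxel-level scans with community structure
#'
#' Voxels sharing a community label share a latent Gaussian signal:
#' voxel series are `w * g_community + sqrt(1 - w^2) * noise`, so the
#' within-community population correlation is `w^2`.  The baseline
#' coupling is set by `mixing` (`w = mixing` at baseline); planted cells
#' raise coupling on the Fisher-z scale exactly as in
#' [simulate_roi_timeseries()]: `r = tanh(atanh(mixing^2) + subject
#' intercept + planted increments)`, `w = sqrt(max(r, 0))`.  Background
#' voxels (label 0) are independent noise.  With `mixing = 1` a
#' community's voxels are exact copies of the latent signal.
#'
#' @param design Scan table from [make_design()].
#' @param grid_shape Integer length-3 grid dimensions.
#' @param community_map Integer label volume matching `grid_shape`;
#'   defaults to [block_community_map()].  A `"networks"` attribute maps
#'   labels to `PMN`/`ATN`; unlabelled communities default to `PMN`.
#' @param effects An [effect_spec()].
#' @param n_timepoints Frames per scan (>= 20).
#' @param mixing Baseline mixing weight in `[0, 1]`; 0 means independent
#'   noise even within communities.
#' @param seed Integer seed.
#' @param voxel_size_mm,tr_s Geometry recorded on each scan.
#' @return List with `series` (named list of [volume_series()]), `scans`
#'   (design with `tsnr`), `mask` (logical 3D array, all `TRUE`) and
#'   `community_map`.
#' @export
simulate_voxel_dataset <- function(design, grid_shape = c(16, 16, 16),
                                   community_map = NULL, effects = effect_spec(),
                                   n_timepoints = 60, mixing = 0.5, seed = 1L,
                                   voxel_size_mm = c(2, 2, 2), tr_s = 2) {
  stopifnot(inherits(effects, "effect_spec"))
  grid_shape <- as.integer(grid_shape)
  if (is.null(community_map)) community_map <- block_community_map(grid_shape)
  if (!identical(dim(community_map), grid_shape)) {
    abort("`community_map` dimensions do not match `grid_shape`.")
  }
  if (n_timepoints < 20) abort("`n_timepoints` must be >= 20.")
  if (mixing < 0 || mixing > 1) abort("`mixing` must be in [0, 1].")
  labels <- sort(unique(as.integer(community_map[community_map > 0])))
  networks <- attr(community_map, "networks") %||%
    setNames(rep("PMN", length(labels)), as.character(labels))
  n_vox <- prod(grid_shape)
  vox_by_label <- lapply(labels, function(l) which(community_map == l))
  with_seed(seed, {
    nuis <- draw_scan_nuisance(design, effects)
    series <- vector("list", nrow(design))
    names(series) <- design$scan_id
    for (i in seq_len(nrow(design))) {
      scan <- design[i, ]
      Y <- matrix(rnorm(n_timepoints * n_vox), n_timepoints, n_vox)
      for (j in seq_along(labels)) {
        w <- community_weight(scan, networks[[as.character(labels[j])]],
                              effects, mixing,
                              nuis$subject_intercept[[as.character(scan$subject_id)]])
        if (w == 0) next
        vox <- vox_by_label[[j]]
        g <- rnorm(n_timepoints)
        if (w >= 1) {
          Y[, vox] <- g
        } else {
          Y[, vox] <- w * g + sqrt(1 - w^2) * Y[, vox]
        }
      }
      Y <- Y * nuis$noise_scale[i]
      series[[i]] <- volume_series(array(t(Y), c(grid_shape, n_timepoints)),
                                   voxel_size_mm, tr_s)
    }
    list(series = series,
         scans = mutate(design, tsnr = nuis$tsnr),
         mask = array(TRUE, grid_shape),
         community_map = community_map)
  })
}

#' Sphere atlas centred on a community map's communities
#'
#' Builds an a-priori sphere atlas (one region per community, named after
#' the community's network) at the community centroids, in the grid's mm
#' coordinates.  Used to classify cluster allegiance on simulated grids.
#'
#' @param community_map Label volume from [block_community_map()].
#' @param voxel_size_mm Grid voxel size.
#' @param radius_mm Sphere radius.
#' @return Atlas tibble (see [read_atlas()]).
#' @export
community_atlas <- function(community_map, voxel_size_mm = c(2, 2, 2),
                            radius_mm = 5) {
  labels <- sort(unique(as.integer(community_map[community_map > 0])))
  networks <- attr(community_map, "networks") %||%
    setNames(rep("PMN", length(labels)), as.character(labels))
  centers <- t(vapply(labels, function(l) {
    colMeans(arrayInd(which(community_map == l), dim(community_map)))
  }, numeric(3)))
  mm <- voxel_coords_mm(centers, voxel_size_mm)
  tibble(name = paste0(unname(networks[as.character(labels)]), "_c", labels),
         network = unname(networks[as.character(labels)]),
         x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3],
         radius_mm = radius_mm)
}

# Mixing weight for one community on one scan.
community_weight <- function(scan, network, effects, mixing, subject_int) {
  if (mixing == 0) return(0)
  if (mixing == 1) return(1)
  z <- atanh(clamp_r(mixing^2)) + subject_int +
    effects$delta_task * (scan$task == "retrieval") +
    effects$delta_3way *
      (network %in% effects$affected_networks &&
         in_planted_cell(scan$group, scan$condition, scan$task))
  r <- tanh(z)
  sqrt(max(r, 0))
}
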