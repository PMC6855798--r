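#' A small built-in ROI atlas for simulated studies
#'
#' Ten 6-mm-radius spherical regions (five posterior-medial, five
#' anterior-temporal) laid out on a 40 mm cube so they fit the default
#' simulation grids without overlapping.  Real analyses supply their own
#' atlas CSV via [read_atlas()].
#'
#' @param radius_mm Sphere radius, default 6 mm.
#' @return An atlas tibble with columns `name`, `network`, `x_mm`, `y_mm`,
#'   `z_mm`, `radius_mm`.
#' @examples
#' synthetic_atlas()
#' @export
synthetic_atlas <- function(radius_mm = 6) {
  centers <- rbind(
    c(8, 8, 8),   c(8, 8, 30),  c(8, 30, 8),  c(30, 8, 8),  c(19, 19, 19),
    c(30, 30, 30), c(30, 30, 8), c(30, 8, 30), c(8, 30, 30), c(19, 19, 33)
  )
  tibble(
    name = c(paste0("PMN_", 1:5), paste0("ATN_", 1:5)),
    network = rep(c("PMN", "ATN"), each = 5),
    x_mm = centers[, 1], y_mm = centers[, 2], z_mm = centers[, 3],
    radius_mm = radius_mm
  )
}

#' Read and validate an ROI atlas CSV
#'
#' The atlas format is one row per region with columns `name`, `network`
#' (`PMN`, `ATN` or `other`), `x_mm`, `y_mm`, `z_mm` and optional
#' `radius_mm` (default 6 mm).
#'
#' @param path CSV path.
#' @return Atlas tibble.
#' @export
read_atlas <- function(path) {
  atlas <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_atlas(atlas)
}

validate_atlas <- function(atlas) {
  needed <- c("name", "network", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(needed, names(atlas))
  if (length(missing)) {
    abort(paste0("atlas lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(atlas$name)) abort("atlas region names must be unique.")
  if (!"radius_mm" %in% names(atlas)) atlas$radius_mm <- 6
  if (any(atlas$radius_mm <= 0)) abort("atlas radii must be positive.")
  as_tibble(atlas)
}

# Population region-by-region correlation matrix for one scan: block
# structure with within-network correlation tanh(z_net) and zero
# between-network correlation.
scan_correlation_matrix <- function(atlas, z_by_network) {
  m <- nrow(atlas)
  R <- diag(m)
  for (net in names(z_by_network)) {
    members <- which(atlas$network == net)
    if (length(members) < 2) next
    r <- tanh(z_by_network[[net]])
    if (r <= -1 / (length(members) - 1)) {
      abort(sprintf(
        "within-network correlation %.3f for '%s' is not positive definite for %d regions.",
        r, net, length(members)))
    }
    R[members, members] <- r
    diag(R)[members] <- 1
  }
  R
}

scan_network_z <- function(scan, networks, effects, subject_intercept) {
  u <- subject_intercept[[as.character(scan$subject_id)]]
  vapply(networks, function(net) {
    z <- effects$baseline_z + u +
      effects$delta_task * (scan$task == "retrieval") +
      effects$delta_3way *
        (net %in% effects$affected_networks &&
           in_planted_cell(scan$group, scan$condition, scan$task))
    z
  }, numeric(1))
}

#' Simulate ROI-level time series with a planted interaction
#'
#' For every scan in `design`, draws `n_timepoints` samples from a
#' multivariate Gaussian whose population correlation between same-network
#' regions is `tanh(baseline_z + subject intercept + planted increments)`
#' and zero between networks.  The planted three-way increment applies
#' only to within-network edges of the affected networks in the
#' (PMN-targeted, stim, retrieval) cell.  A per-scan log-normal noise
#' scale varies the marginal SD (not the correlations) and is recorded as
#' the tSNR covariate.
#'
#' @param design Scan table from [make_design()].
#' @param atlas Atlas tibble; needs >= 2 regions per simulated network.
#' @param effects An [effect_spec()].
#' @param n_timepoints Frames per scan (>= 20).
#' @param seed Integer seed.
#' @return A list with `series` (named list of region x time matrices,
#'   one per scan), and `scans` (the design with `tsnr` appended).
#' @examples
#' sim <- simulate_roi_timeseries(make_design(2), synthetic_atlas(),
#'                                effect_spec(), n_timepoints = 50, seed = 1)
#' dim(sim$series[[1]])
#' @export
simulate_roi_timeseries <- function(design, atlas, effects,
                                    n_timepoints = 300, seed = 1L) {
  atlas <- validate_atlas(atlas)
  stopifnot(inherits(effects, "effect_spec"))
  if (n_timepoints < 20) abort("`n_timepoints` must be >= 20.")
  networks <- intersect(unique(atlas$network), c("PMN", "ATN"))
  counts <- table(atlas$network[atlas$network %in% networks])
  if (any(counts < 2)) abort("atlas needs >= 2 regions per network.")
  with_seed(seed, {
    nuis <- draw_scan_nuisance(design, effects)
    series <- vector("list", nrow(design))
    names(series) <- design$scan_id
    for (i in seq_len(nrow(design))) {
      scan <- design[i, ]
      z <- scan_network_z(scan, networks, effects, nuis$subject_intercept)
      R <- scan_correlation_matrix(atlas, as.list(z))
      L <- chol(R)
      X <- matrix(rnorm(n_timepoints * nrow(atlas)), n_timepoints) %*% L
      X <- X * nuis$noise_scale[i]
      mat <- t(X)
      rownames(mat) <- atlas$name
      series[[i]] <- mat
    }
    list(series = series,
         scans = mutate(design, tsnr = nuis$tsnr))
  })
}
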