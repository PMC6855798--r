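#' Seed-based driver correlation map
#'
#' Correlates the spatial-average time series of a seed cluster with
#' every in-mask voxel and Fisher-z transforms the result, one map per
#' scan.
#'
#' @param series A [volume_series()].
#' @param seed_voxels Integer `n x 3` voxel-index matrix (nonempty).
#' @param mask Logical 3D array.
#' @return 3D Fisher-z array (`NA` off-mask).
#' @export
seed_driver_map <- function(series, seed_voxels, mask = NULL) {
  stopifnot(is_volume_series(series))
  seed_ts <- extract_mean_timeseries(series, seed_voxels)
  if (sd(seed_ts) == 0) abort("seed time series has zero variance.")
  d <- vol_dims(series)
  if (is.null(mask)) mask <- array(TRUE, d)
  idx <- which(mask != 0)
  Y <- as_time_by_voxel(series)[, idx, drop = FALSE]
  sds <- apply(Y, 2, sd)
  r <- rep(NA_real_, length(idx))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.numeric(cor(seed_ts, Y[, ok, drop = FALSE]))
  out <- array(NA_real_, d)
  out[idx] <- atanh(clamp_r(r))
  out
}

#' Driver inference on seed maps
#'
#' Voxelwise model on the per-scan seed-correlation maps at the strict
#' driver threshold: two-tailed voxel p < 0.001 and a fixed extent of 20
#' contiguous voxels (no permutation at this stage).
#'
#' @param maps Named list of seed maps (one per scan) or matrix.
#' @param scans Scan tibble.
#' @param mask Logical 3D array.
#' @param model Model for the refit (`"twoway"` within one group by
#'   default, matching per-group driver analyses).
#' @param p_two_tailed Voxel threshold (default 0.001).
#' @param min_extent Cluster extent threshold in voxels (default 20).
#' @param connectivity Cluster adjacency.
#' @param method Voxelwise fit method (see [voxelwise_lme()]).
#' @return A `cluster_set` of surviving driver clusters (the full
#'   `stat_map` in attribute `"statmap"`).
#' @export
driver_inference <- function(maps, scans, mask, model = "twoway",
                             p_two_tailed = 0.001, min_extent = 20,
                             connectivity = 6, method = "ols") {
  statmap <- voxelwise_lme(maps, scans, mask, model = model, method = method)
  clusters <- threshold_and_label(statmap, p_two_tailed, connectivity)
  out <- apply_cutoff(clusters, min_extent)
  attr(out, "statmap") <- statmap
  out
}

#' Classify cluster network allegiance
#'
#' Two-step rule: a cluster sharing at least `min_overlap` voxels with
#' any a-priori PMN or ATN sphere is assigned to that network (ties by
#' larger overlap count, then PMN; ties are recorded); otherwise it
#' takes the label of the reference-network volume with maximal overlap;
#' a cluster overlapping nothing is `unassigned`.
#'
#' @param clusters A `cluster_set`.
#' @param atlas Atlas tibble of a-priori spheres (PMN/ATN).
#' @param reference_networks Optional integer label volume of reference
#'   resting-state networks, same grid as the clusters.
#' @param reference_legend Named character vector mapping label values
#'   to network names (defaults to `"net<label>"`).
#' @param voxel_size_mm,origin_mm Grid geometry for the atlas spheres.
#' @param min_overlap Minimum shared voxels for an a-priori assignment.
#' @return `AllegianceTable` tibble: `cluster_id`, `size`, per-candidate
#'   overlap counts, assigned `label`, `tie` flag.
#' @export
classify_allegiance <- function(clusters, atlas, reference_networks = NULL,
                                reference_legend = NULL,
                                voxel_size_mm = c(2, 2, 2),
                                origin_mm = c(0, 0, 0), min_overlap = 1) {
  stopifnot(inherits(clusters, "cluster_set"))
  atlas <- validate_atlas(atlas)
  d <- dim(clusters$labels)
  if (!is.null(reference_networks) && !identical(dim(reference_networks), d)) {
    abort("`reference_networks` is not in the same space as the clusters.")
  }
  networks <- intersect(unique(atlas$network), c("PMN", "ATN"))
  sphere_masks <- lapply(networks, function(net) {
    m <- array(FALSE, d)
    for (i in which(atlas$network == net)) {
      vox <- sphere_voxels(c(atlas$x_mm[i], atlas$y_mm[i], atlas$z_mm[i]),
                           atlas$radius_mm[i], d, voxel_size_mm, origin_mm,
                           region = atlas$name[i])
      m[vox] <- TRUE
    }
    m
  })
  names(sphere_masks) <- networks
  rows <- purrr::map(clusters$clusters$id, function(id) {
    vox <- which(clusters$labels == id)
    counts <- vapply(sphere_masks, function(m) sum(m[vox]), numeric(1))
    tie <- FALSE
    if (any(counts >= min_overlap)) {
      best <- counts == max(counts)
      tie <- sum(best) > 1
      # a-priori spheres take precedence; ties resolved toward PMN
      label <- if (tie && "PMN" %in% names(counts)[best]) "PMN"
               else names(counts)[which.max(counts)]
      ref_label <- NA_character_; ref_overlap <- NA_real_
    } else if (!is.null(reference_networks)) {
      ref <- reference_networks[vox]
      ref <- ref[ref > 0]
      if (length(ref)) {
        tab <- table(ref)
        top <- names(tab)[which.max(tab)]
        legend <- reference_legend %||%
          setNames(paste0("net", sort(unique(as.integer(reference_networks[reference_networks > 0])))),
                   sort(unique(as.integer(reference_networks[reference_networks > 0]))))
        label <- unname(legend[top])
        ref_label <- label; ref_overlap <- max(tab)
      } else {
        label <- "unassigned"; ref_label <- NA_character_; ref_overlap <- 0
      }
    } else {
      label <- "unassigned"; ref_label <- NA_character_; ref_overlap <- NA_real_
    }
    if (tie) {
      inform(sprintf("cluster %d: overlap tie resolved to '%s'.", id, label))
    }
    tibble(cluster_id = id, size = length(vox),
           overlap_pmn = if ("PMN" %in% networks) counts[["PMN"]] else 0,
           overlap_atn = if ("ATN" %in% networks) counts[["ATN"]] else 0,
           ref_label = ref_label, ref_overlap = ref_overlap,
           label = label, tie = tie)
  })
  if (!length(rows)) {
    return(tibble(cluster_id = integer(), size = integer(),
                  overlap_pmn = numeric(), overlap_atn = numeric(),
                  ref_label = character(), ref_overlap = numeric(),
                  label = character(), tie = logical()))
  }
  list_rbind(rows)
}

#' Fraction of clusters overlapping a reference volume
#'
#' @param clusters A `cluster_set`.
#' @param reference Binary 3D array in the same space.
#' @param unit Count `"clusters"` sharing >= 1 voxel (default) or the
#'   `"voxels"` fraction inside the reference.
#' @return Scalar fraction, or `NA` (with a message) for an empty set.
#' @export
overlap_fraction <- function(clusters, reference,
                             unit = c("clusters", "voxels")) {
  unit <- match.arg(unit)
  stopifnot(inherits(clusters, "cluster_set"))
  if (!identical(dim(reference), dim(clusters$labels))) {
    abort("`reference` is not in the same space as the clusters.")
  }
  if (!nrow(clusters$clusters)) {
    inform("empty cluster set: overlap fraction undefined.")
    return(NA_real_)
  }
  if (unit == "clusters") {
    hits <- vapply(clusters$clusters$id, function(id) {
      any(reference[clusters$labels == id] != 0)
    }, logical(1))
    mean(hits)
  } else {
    vox <- clusters$labels > 0
    sum(reference[vox] != 0) / sum(vox)
  }
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Continuity-corrected chi-square: `sum((|O - E| - 0.5)^2 / E)` with the
#' correction floored at zero when `|O - E| < 0.5`, referred to the
#' chi-square distribution with 1 df.  Used to compare the PMN/ATN
#' distribution of driver regions between stimulation-target groups.
#'
#' @param table 2x2 matrix of non-negative counts with positive
#'   marginals (rows = stimulation target, columns = network).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' yates_chi2(matrix(c(31, 12, 5, 13), 2))
#' @export
yates_chi2 <- function(table) {
  m <- as.matrix(table)
  if (!identical(dim(m), c(2L, 2L))) abort("`table` must be 2x2.")
  if (any(m < 0) || any(!is.finite(m))) abort("counts must be non-negative.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("all marginals must be positive.")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  tibble(statistic = unname(ht$statistic), df = 1L,
         p_value = unname(ht$p.value))
}
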