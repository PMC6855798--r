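neighbor_offsets <- function(connectivity = c(6, 18, 26)) {
  connectivity <- match.arg(as.character(connectivity), c("6", "18", "26"))
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(connectivity,
         "6" = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g)
}

#' Label connected components in a 3D binary volume
#'
#' Components under face (6), edge (18) or corner (26) adjacency, found
#' by building the voxel adjacency graph and taking its connected
#' components.
#'
#' @param mask 3D logical/binary array.
#' @param connectivity 6 (default), 18 or 26.
#' @return Integer label array (0 = background); component sizes in the
#'   `"sizes"` attribute (named by label).
#' @export
label_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  idx <- which(mask != 0)
  labels <- array(0L, d)
  if (!length(idx)) {
    attr(labels, "sizes") <- integer(0)
    return(labels)
  }
  pos <- array(0L, d)
  pos[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  offs <- neighbor_offsets(connectivity)
  # keep one direction per neighbour pair to avoid duplicate edges
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ,
               drop = FALSE]
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] + (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_pos <- pos[nb_lin]
    hit <- nb_pos > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nb_pos[hit])
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  membership <- igraph::components(g)$membership
  labels[idx] <- as.integer(membership)
  attr(labels, "sizes") <- as.integer(table(membership))
  labels
}

#' Threshold a statistic map and label clusters
#'
#' Voxels with two-tailed `p` below the threshold (both signs pooled by
#' default) form the suprathreshold set; connected components become
#' clusters with size, peak-|t| location, mean effect and a sign summary.
#'
#' @param statmap A `stat_map` from [voxelwise_lme()].
#' @param p_two_tailed Voxelwise threshold (default 0.05).
#' @param connectivity Cluster adjacency: 6 (default), 18 or 26.
#' @param sign_split Cluster positive and negative voxels separately?
#' @return A `cluster_set`: `labels` array and a `clusters` tibble
#'   (`id`, `size`, `peak_t`, peak voxel indices, `mean_beta`, `sign`).
#'   An empty set (no suprathreshold voxels) is valid.
#' @export
threshold_and_label <- function(statmap, p_two_tailed = 0.05,
                                connectivity = 6, sign_split = FALSE) {
  stopifnot(inherits(statmap, "stat_map"))
  supra <- !is.na(statmap$p) & statmap$p < p_two_tailed
  if (sign_split) {
    lab_pos <- label_components(supra & statmap$t > 0, connectivity)
    lab_neg <- label_components(supra & statmap$t < 0, connectivity)
    labels <- lab_pos
    n_pos <- max(lab_pos)
    labels[lab_neg > 0] <- lab_neg[lab_neg > 0] + n_pos
  } else {
    labels <- label_components(supra, connectivity)
  }
  cluster_set(labels, statmap)
}

cluster_set <- function(labels, statmap = NULL) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  d <- dim(labels)
  rows <- purrr::map(ids, function(id) {
    vox <- which(labels == id)
    tv <- if (!is.null(statmap)) statmap$t[vox] else rep(NA_real_, length(vox))
    bv <- if (!is.null(statmap)) statmap$beta[vox] else rep(NA_real_, length(vox))
    peak_idx <- if (all(is.na(tv))) 1L else which.max(abs(tv))
    pc <- arrayInd(vox[peak_idx], d)
    tibble(id = id, size = length(vox), peak_t = tv[peak_idx],
           peak_x = pc[1], peak_y = pc[2], peak_z = pc[3],
           mean_beta = mean(bv),
           sign = if (all(is.na(tv))) NA_character_
                  else if (all(tv >= 0, na.rm = TRUE)) "pos"
                  else if (all(tv <= 0, na.rm = TRUE)) "neg" else "mixed")
  })
  clusters <- if (length(rows)) list_rbind(rows) else
    tibble(id = integer(), size = integer(), peak_t = numeric(),
           peak_x = integer(), peak_y = integer(), peak_z = integer(),
           mean_beta = numeric(), sign = character())
  structure(list(labels = labels, clusters = clusters),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s), %d suprathreshold voxel(s)\n",
              nrow(x$clusters), sum(x$clusters$size)))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, ...) x$clusters

#' Apply a cluster-extent cutoff
#'
#' Retains clusters whose size is at least `cutoff` voxels ("that size
#' or larger").
#'
#' @param clusters A `cluster_set`.
#' @param cutoff Minimum cluster size (>= 1).
#' @return A filtered `cluster_set`.
#' @export
apply_cutoff <- function(clusters, cutoff) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (!is.numeric(cutoff) || cutoff < 1) abort("`cutoff` must be >= 1.")
  keep <- clusters$clusters$id[clusters$clusters$size >= cutoff]
  labels <- clusters$labels
  labels[!(labels %in% keep)] <- 0L
  structure(list(labels = labels,
                 clusters = clusters$clusters[clusters$clusters$size >= cutoff, ]),
            class = "cluster_set")
}
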