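# Shared fixture builders; everything is generated in code.

# voxel-major matrix (V x T) -> volume_series on dims
series_from_matrix <- function(vt, dims, voxel_size = 2, tr = 0.5) {
  vt <- as.matrix(vt)
  stopifnot(prod(dims) == nrow(vt))
  volume_series(array(vt, c(dims, ncol(vt))), voxel_size_mm = voxel_size,
                tr_s = tr)
}

# Hand-built stat_map for thresholding/cluster tests.
toy_stat_map <- function(p, t = NULL, beta = NULL, mask = NULL) {
  d <- dim(p)
  structure(list(beta = if (is.null(beta)) array(0, d) else beta,
                 t = if (is.null(t)) array(0, d) else t,
                 p = p, df = 10, term = "condition:task:group",
                 model = "threeway", method = "ols",
                 mask = if (is.null(mask)) array(TRUE, d) else mask),
            class = "stat_map")
}

# Independent flood-fill component labeller (explicit stack), used as
# the oracle for label_components().
flood_fill_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  offs <- taskconn:::neighbor_offsets(connectivity)
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] > 0) next
    cur <- cur + 1L
    stack <- list(arrayInd(start, d)[1, ])
    lab[start] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        q <- p + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        lin <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[lin] != 0 && lab[lin] == 0) {
          lab[lin] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Long connectivity table with a planted cell effect, built directly on
# the Fisher-z scale (bypasses the time-series generators for speed).
direct_network_table <- function(n_per_group, delta = 0, subject_sd = 0.1,
                                 noise_sd = 0.05, seed = 1, tsnr_sd = 5) {
  design <- make_design(n_per_group, seed = seed)
  withr::with_seed(seed * 13 + 1, {
    n <- nrow(design)
    u <- stats::rnorm(2 * n_per_group, 0, subject_sd)
    design$value <- 0.2 + u[design$subject_id] +
      delta * (design$group == "PMN" & design$condition == "stim" &
                 design$task == "retrieval") +
      stats::rnorm(n, 0, noise_sd)
    design$tsnr <- stats::rnorm(n, 100, tsnr_sd)
    design
  })
}
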