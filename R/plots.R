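# ggplot2 methods for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_histogram
#'   geom_vline geom_point geom_abline geom_raster facet_wrap labs
#'   scale_fill_gradient2 theme_minimal coord_fixed
#' @export
ggplot2::autoplot

#' @method autoplot conn_matrix
#' @export
autoplot.conn_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(unclass(object)))
  names(df) <- c("region_a", "region_b", "z")
  ggplot(df, aes(.data$region_a, .data$region_b, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "Fisher z",
         title = "Region-pair connectivity") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @method autoplot permutation_null
#' @export
autoplot.permutation_null <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(.data$max_cluster_size)) +
    geom_histogram(binwidth = 1, fill = "grey60", colour = "white") +
    geom_vline(xintercept = object$cutoff, colour = "firebrick",
               linetype = 2) +
    facet_wrap(~term) +
    labs(x = "max cluster size under permutation (voxels)", y = "count",
         title = sprintf("Cluster-extent null (cutoff %d voxels at alpha %.2g)",
                         as.integer(object$cutoff), object$alpha)) +
    theme_minimal()
}

#' @method autoplot robust_fit
#' @export
autoplot.robust_fit <- function(object, ...) {
  df <- tibble(effect = object$fit$model$interaction_effect,
               change = object$fit$model$memory_change)
  ggplot(df, aes(.data$effect, .data$change)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "firebrick") +
    labs(x = "connectivity interaction effect (Fisher z)",
         y = "context recollection change (post-stim - post-sham)",
         title = sprintf("Robust fit: F(%d, %d) = %.2f, p = %.3g, r^2 = %.2f",
                         object$df[1], object$df[2], object$f_statistic,
                         object$p_value, object$r_squared)) +
    theme_minimal()
}

#' Plot axial slices of a statistic map
#'
#' @param statmap A `stat_map` from [voxelwise_lme()].
#' @param what `"t"`, `"beta"` or `"p"`.
#' @param slices Which z slices (default: four evenly spaced).
#' @return A ggplot object.
#' @export
plot_stat_map <- function(statmap, what = c("t", "beta", "p"),
                          slices = NULL) {
  stopifnot(inherits(statmap, "stat_map"))
  what <- match.arg(what)
  vol <- statmap[[what]]
  d <- dim(vol)
  slices <- slices %||% unique(round(seq(1, d[3], length.out = 4)))
  df <- purrr::map(slices, function(z) {
    sl <- vol[, , z]
    tibble(x = rep(seq_len(d[1]), d[2]),
           y = rep(seq_len(d[2]), each = d[1]),
           value = as.vector(sl), slice = z)
  }) |> list_rbind()
  ggplot(df, aes(.data$x, .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "steelblue", mid = "white",
                         high = "firebrick", na.value = "grey90") +
    facet_wrap(~slice, labeller = ggplot2::label_both) +
    coord_fixed() +
    labs(title = sprintf("%s map for %s", what, statmap$term),
         fill = what) +
    theme_minimal()
}
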