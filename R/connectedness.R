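#' Global connectedness map
#'
#' For every in-mask voxel, the mean Pearson correlation of its time
#' series with every other in-mask voxel, Fisher-z transformed and stored
#' back into the voxel.  Two computation paths give identical results
#' away from the clamp: `"matrix"` forms the full standardized-data
#' cross-product (clamping each pairwise correlation before averaging,
#' exactly matching the brute-force double loop) and `"fast"` uses the
#' row-sum identity `sum_j r(i, j) = z_i . sum_j z_j` on unit-normalised
#' series, which is O(time x voxels) and clamps the mean.  `"auto"`
#' picks `"matrix"` up to 1024 in-mask voxels.
#'
#' Zero-variance voxels are removed from the mask with a warning.
#'
#' @param series A [volume_series()].
#' @param mask Logical 3D array (>= 2 in-mask voxels); default whole
#'   grid.
#' @param method `"auto"`, `"matrix"` or `"fast"`.
#' @return 3D array of Fisher-z connectedness (`NA` outside the mask),
#'   with the effective mask in attribute `"mask"`.
#' @examples
#' vs <- volume_series(array(rnorm(5 * 5 * 5 * 30), c(5, 5, 5, 30)))
#' gc_map <- global_connectedness(vs)
#' @export
global_connectedness <- function(series, mask = NULL,
                                 method = c("auto", "matrix", "fast")) {
  method <- match.arg(method)
  stopifnot(is_volume_series(series))
  if (n_frames(series) < 3) abort("need >= 3 frames.")
  d <- vol_dims(series)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!identical(dim(mask), d)) abort("mask shape mismatch.")
  idx <- which(mask != 0)
  Y <- as_time_by_voxel(series)[, idx, drop = FALSE]
  Yc <- sweep(Y, 2, colMeans(Y))
  norms <- sqrt(colSums(Yc^2))
  if (any(norms == 0)) {
    warn(sprintf("%d zero-variance voxel(s) removed from the mask.",
                 sum(norms == 0)))
    idx <- idx[norms > 0]
    Yc <- Yc[, norms > 0, drop = FALSE]
    norms <- norms[norms > 0]
  }
  v <- length(idx)
  if (v < 2) abort("need >= 2 usable in-mask voxels.")
  if (method == "auto") method <- if (v <= 1024) "matrix" else "fast"
  Z <- sweep(Yc, 2, norms, `/`)  # unit-norm columns: crossprod(Z) = cor(Y)
  if (method == "matrix") {
    R <- clamp_r(crossprod(Z))
    mean_r <- (colSums(R) - diag(R)) / (v - 1)
  } else {
    u <- rowSums(Z)
    mean_r <- (as.numeric(crossprod(Z, u)) - 1) / (v - 1)
  }
  out <- array(NA_real_, d)
  out[idx] <- atanh(clamp_r(mean_r))
  eff_mask <- array(FALSE, d)
  eff_mask[idx] <- TRUE
  attr(out, "mask") <- eff_mask
  out
}

# Design matrix for the voxelwise models; mirrors fit_lme's fixed-effect
# structure (sum-to-zero +/-0.5 coding, centred tSNR).
voxelwise_design <- function(scans, model = c("threeway", "twoway"),
                             use_tsnr = TRUE) {
  model <- match.arg(model)
  dat <- code_lme_factors(scans)
  if (model == "threeway") {
    X <- cbind(cond = dat$cond_c, task = dat$task_c, group = dat$group_c,
               "condition:task" = dat$cond_c * dat$task_c,
               "condition:group" = dat$cond_c * dat$group_c,
               "task:group" = dat$task_c * dat$group_c,
               "condition:task:group" = dat$cond_c * dat$task_c * dat$group_c)
    colnames(X)[1:3] <- c("condition", "task", "group")
  } else {
    X <- cbind(condition = dat$cond_c, task = dat$task_c,
               "condition:task" = dat$cond_c * dat$task_c)
  }
  if (use_tsnr && "tsnr" %in% names(scans) && sd(dat$tsnr_c) > 0) {
    X <- cbind(X, tsnr = dat$tsnr_c)
  }
  list(X = X, subject = as.character(scans$subject_id))
}

# Subtract per-subject means from the rows of a matrix (rows = scans).
center_by_subject <- function(M, subj) {
  M <- as.matrix(M)
  sums <- rowsum(M, subj)
  counts <- as.vector(table(subj)[rownames(sums)])
  M - (sums / counts)[subj, , drop = FALSE]
}

# Vectorised per-voxel OLS with subject-mean centring: the subject random
# intercept is projected out of both sides, then all voxels are fit with
# one set of matrix products.  Returns beta, t, p for `term` plus the
# residual df.  `Yc` may be supplied pre-centred (it does not change when
# design labels are permuted within subjects).
fast_voxel_fit <- function(Y, scans, model = "threeway",
                           term = NULL, use_tsnr = TRUE, Yc = NULL) {
  des <- voxelwise_design(scans, model, use_tsnr)
  term <- term %||% if (model == "threeway") "condition:task:group" else "condition:task"
  subj <- des$subject
  Xc <- center_by_subject(des$X, subj)
  colnames(Xc) <- colnames(des$X)
  keep <- colSums(Xc^2) > 1e-10
  if (!keep[term]) {
    abort(sprintf("term '%s' is not estimable after subject centring.", term))
  }
  Xc <- Xc[, keep, drop = FALSE]
  if (is.null(Yc)) Yc <- center_by_subject(Y, subj)
  rank <- qr(Xc)$rank
  if (rank < ncol(Xc)) abort("collinear design after subject centring.")
  df <- nrow(Yc) - length(unique(subj)) - rank
  if (df <= 0) abort("no residual degrees of freedom.")
  XtX_inv <- solve(crossprod(Xc))
  B <- XtX_inv %*% crossprod(Xc, Yc)
  resid <- Yc - Xc %*% B
  sigma2 <- colSums(resid^2) / df
  j <- match(term, colnames(Xc))
  se <- sqrt(XtX_inv[j, j] * sigma2)
  beta <- B[j, ]
  tval <- ifelse(se > 0, beta / se, 0)
  list(beta = beta, t = tval, df = df,
       p = 2 * pt(-abs(tval), df), term = term)
}

#' Voxelwise mixed-model statistic map
#'
#' Fits the connectivity model at every in-mask voxel of a stack of
#' per-scan maps (e.g. global-connectedness volumes) and returns the
#' requested term's effect, t and p volumes.  `method = "lme"` fits the
#' full REML mixed model per voxel via [fit_lme()]; `method = "ols"`
#' (default) uses the subject-mean-centred OLS described in the methods
#' vignette, which removes the subject intercept exactly in this
#' balanced design and is fast enough to repeat under permutation.  The
#' same statistic is used for observed and permuted data so that
#' cluster-extent inference compares like with like.
#'
#' @param maps Named list of 3D arrays (one per scan, keyed by
#'   `scan_id`) or a `n_scans x voxels` matrix over the mask.
#' @param scans Scan tibble (`scan_id`, factors, `tsnr`).
#' @param mask Logical 3D array.
#' @param model `"threeway"` or `"twoway"`.
#' @param term Term to map; defaults to the model's interaction.
#' @param method `"ols"` or `"lme"`.
#' @param use_tsnr Include the tSNR covariate?
#' @return A `stat_map`: list with 3D `beta`, `t`, `p` arrays (`NA`
#'   off-mask), `df`, `term`, `model`, `method`, `mask`.
#' @export
voxelwise_lme <- function(maps, scans, mask, model = c("threeway", "twoway"),
                          term = NULL, method = c("ols", "lme"),
                          use_tsnr = TRUE) {
  model <- match.arg(model)
  method <- match.arg(method)
  Y <- maps_to_matrix(maps, scans, mask)
  d <- dim(mask)
  term <- term %||% if (model == "threeway") "condition:task:group" else "condition:task"
  if (method == "ols") {
    fit <- fast_voxel_fit(Y, scans, model, term, use_tsnr)
    beta <- fit$beta; tval <- fit$t; pval <- fit$p; df <- fit$df
  } else {
    v <- ncol(Y)
    beta <- tval <- pval <- rep(NA_real_, v)
    df <- NA_real_
    dropped <- 0L
    for (i in seq_len(v)) {
      tab <- mutate(scans, value = Y[, i])
      row <- tryCatch({
        f <- fit_lme(tab, model = model, use_tsnr = use_tsnr)
        lme_term(f, term)
      }, error = function(e) NULL)
      if (is.null(row)) { dropped <- dropped + 1L; next }
      beta[i] <- row$estimate; tval[i] <- row$statistic
      pval[i] <- row$p_value; df <- row$df
    }
    if (dropped > 0) {
      warn(sprintf("%d voxel fit(s) failed and were masked out.", dropped))
    }
  }
  idx <- which(mask != 0)
  mk <- function(vals) { a <- array(NA_real_, d); a[idx] <- vals; a }
  structure(list(beta = mk(beta), t = mk(tval), p = mk(pval), df = df,
                 term = term, model = model, method = method, mask = mask),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> term '%s' (%s model, %s fit), %d in-mask voxels\n",
              x$term, x$model, x$method, sum(x$mask)))
  invisible(x)
}

# Accept a list of 3D arrays or a ready matrix; rows ordered like scans.
maps_to_matrix <- function(maps, scans, mask) {
  idx <- which(mask != 0)
  if (is.matrix(maps)) {
    if (nrow(maps) != nrow(scans)) abort("one map row per scan required.")
    return(maps)
  }
  if (!all(scans$scan_id %in% names(maps))) {
    abort("`maps` must be keyed by scan_id, one per scan.")
  }
  out <- matrix(NA_real_, nrow(scans), length(idx))
  for (i in seq_len(nrow(scans))) {
    out[i, ] <- maps[[scans$scan_id[i]]][idx]
  }
  if (!all(is.finite(out))) abort("non-finite map values inside the mask.")
  out
}
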