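#' Randomly flip design factor labels
#'
#' One draw of the permutation scheme used for the cluster-extent null:
#' within each subject the stim/sham labels are swapped with probability
#' 1/2, within each subject-condition the retrieval/rest labels are
#' swapped with probability 1/2, and the group labels are permuted
#' across subjects (preserving group sizes).  Each component can be
#' switched off to explore alternative schemes.
#'
#' @param scans Scan tibble.
#' @param flip_condition,flip_task,permute_group Scheme components.
#' @return Scan tibble with relabelled factors (`tsnr` and `scan_id`
#'   stay attached to their scans).
#' @export
permute_scan_labels <- function(scans, flip_condition = TRUE,
                                flip_task = TRUE, permute_group = TRUE) {
  out <- scans
  subjects <- unique(out$subject_id)
  if (flip_condition) {
    flip <- subjects[runif(length(subjects)) < 0.5]
    sel <- out$subject_id %in% flip
    out$condition[sel] <- ifelse(out$condition[sel] == "stim", "sham", "stim")
  }
  if (flip_task) {
    cells <- unique(out[, c("subject_id", "condition")])
    flip <- runif(nrow(cells)) < 0.5
    key <- paste(out$subject_id, out$condition)
    sel <- key %in% paste(cells$subject_id, cells$condition)[flip]
    out$task[sel] <- ifelse(out$task[sel] == "retrieval", "rest", "retrieval")
  }
  if (permute_group && "group" %in% names(out)) {
    grp <- out$group[match(subjects, out$subject_id)]
    new_grp <- setNames(sample(grp), as.character(subjects))
    out$group <- new_grp[as.character(out$subject_id)]
  }
  out
}

cutoff_from_max_sizes <- function(max_sizes, alpha) {
  ks <- seq_len(max(max_sizes, 0) + 1L)
  exceed <- vapply(ks, function(k) mean(max_sizes >= k), numeric(1))
  ks[which(exceed <= alpha)[1]]
}

#' Permutation cluster-extent null and size cutoff
#'
#' Builds the null distribution of the maximum suprathreshold cluster
#' size by refitting the voxelwise model `n_permutations` times with
#' randomly flipped factor labels ([permute_scan_labels()]), thresholding
#' each permuted map at the same two-tailed voxel threshold as the
#' observed analysis, and recording the largest cluster (0 if none).
#' The cutoff is the smallest size whose exceedance probability is at
#' most `alpha`; when several terms are tested the most stringent
#' (largest) per-term cutoff is reported as `cutoff`.
#'
#' @param maps Named list of per-scan 3D maps or `n_scans x voxels`
#'   matrix (see [voxelwise_lme()]).
#' @param scans Scan tibble.
#' @param mask Logical 3D array.
#' @param model `"threeway"` or `"twoway"`.
#' @param terms Model terms to test (default: the interaction).
#' @param n_permutations Number of permutations (default 1000; at least
#'   `min_permutations`).
#' @param alpha Cluster-level familywise level (default 0.05).
#' @param p_two_tailed Voxelwise threshold (default 0.05).
#' @param connectivity Cluster adjacency (6, 18, 26).
#' @param seed Integer seed; fixed seed gives an identical permutation
#'   sequence and cutoff.
#' @param min_permutations Floor below which the null is not reportable.
#' @param use_tsnr Include the tSNR covariate in the refits?
#' @param method Per-permutation refit: `"ols"` (subject-centred OLS,
#'   default) or `"lme"` (full REML refit per voxel; used to validate
#'   the fast path on small test beds).
#' @return A `permutation_null`: per-term max-size matrix, per-term
#'   cutoffs, the stringent `cutoff`, and the scheme metadata.
#' @export
permutation_cluster_cutoff <- function(maps, scans, mask,
                                       model = c("threeway", "twoway"),
                                       terms = NULL, n_permutations = 1000,
                                       alpha = 0.05, p_two_tailed = 0.05,
                                       connectivity = 6, seed = 1L,
                                       min_permutations = 100,
                                       use_tsnr = TRUE,
                                       method = c("ols", "lme")) {
  model <- match.arg(model)
  method <- match.arg(method)
  if (n_permutations < min_permutations) {
    abort(sprintf("need >= %d permutations for a reportable cutoff.",
                  min_permutations))
  }
  terms <- terms %||% if (model == "threeway") "condition:task:group" else "condition:task"
  Y <- maps_to_matrix(maps, scans, mask)
  subj <- as.character(scans$subject_id)
  Yc <- center_by_subject(Y, subj)
  d <- dim(mask)
  idx <- which(mask != 0)
  max_sizes <- matrix(0L, n_permutations, length(terms),
                      dimnames = list(NULL, terms))
  with_seed(seed, {
    for (p in seq_len(n_permutations)) {
      perm <- permute_scan_labels(scans)
      for (term in terms) {
        fit <- if (method == "ols") {
          fast_voxel_fit(Y, perm, model, term, use_tsnr, Yc = Yc)
        } else {
          sm <- suppressWarnings(
            voxelwise_lme(Y, mutate(perm, scan_id = scans$scan_id), mask,
                          model = model, term = term, method = "lme",
                          use_tsnr = use_tsnr))
          list(p = sm$p[idx])
        }
        supra_lin <- idx[fit$p < p_two_tailed]
        if (!length(supra_lin)) next
        supra <- array(FALSE, d)
        supra[supra_lin] <- TRUE
        sizes <- attr(label_components(supra, connectivity), "sizes")
        max_sizes[p, term] <- max(sizes)
      }
    }
  })
  cutoffs <- vapply(terms, function(term) {
    cutoff_from_max_sizes(max_sizes[, term], alpha)
  }, numeric(1))
  structure(
    list(max_sizes = max_sizes, cutoffs = cutoffs,
         cutoff = max(cutoffs), alpha = alpha,
         p_two_tailed = p_two_tailed, connectivity = connectivity,
         n_permutations = n_permutations, seed = seed, model = model,
         scheme = "within-subject condition/task flips + group permutation",
         fit_method = if (method == "ols") "subject-centred OLS"
                      else "per-voxel REML"),
    class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("<permutation_null> %d permutations, alpha %.3g, cutoff %d voxel(s)\n",
              x$n_permutations, x$alpha, as.integer(x$cutoff)))
  for (term in names(x$cutoffs)) {
    cat(sprintf("  %-24s cutoff %d\n", term, as.integer(x$cutoffs[[term]])))
  }
  invisible(x)
}

#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) {
  tibble(term = rep(colnames(x$max_sizes), each = nrow(x$max_sizes)),
         permutation = rep(seq_len(nrow(x$max_sizes)), ncol(x$max_sizes)),
         max_cluster_size = as.integer(x$max_sizes))
}

#' Familywise-error simulation for the cluster-extent procedure
#'
#' Generates `n_studies` null synthetic studies (no planted interaction),
#' runs the full pipeline on each — per-scan global-connectedness maps,
#' observed voxelwise interaction map, permutation cutoff, surviving
#' clusters — and records whether any cluster survives.  The surviving
#' fraction estimates the procedure's familywise error at level `alpha`.
#'
#' @param n_studies Number of replicate null studies.
#' @param n_per_group Subjects per group in each study.
#' @param grid_shape Simulation grid.
#' @param n_timepoints Frames per scan.
#' @param n_permutations Permutations per study.
#' @param alpha,p_two_tailed,connectivity Inference parameters.
#' @param effects Null [effect_spec()] (default: `delta_3way = 0`).
#' @param mixing Baseline community coupling of the simulated grids.
#' @param seed Integer seed (per-study seeds are derived from it).
#' @return Tibble per study: `study`, `cutoff`, `max_observed`,
#'   `survived`.
#' @export
cluster_fwe_simulation <- function(n_studies = 100, n_per_group = 8,
                                   grid_shape = c(16, 16, 16),
                                   n_timepoints = 60, n_permutations = 200,
                                   alpha = 0.05, p_two_tailed = 0.05,
                                   connectivity = 6,
                                   effects = effect_spec(delta_3way = 0),
                                   mixing = 0.5, seed = 1L) {
  purrr::map(seq_len(n_studies), function(s) {
    study_seed <- derive_seed(seed, s)
    design <- make_design(n_per_group, seed = study_seed)
    sim <- simulate_voxel_dataset(design, grid_shape, effects = effects,
                                  n_timepoints = n_timepoints,
                                  mixing = mixing, seed = study_seed)
    maps <- lapply(sim$series, function(vs) {
      global_connectedness(vs, sim$mask, method = "fast")
    })
    statmap <- voxelwise_lme(maps, sim$scans, sim$mask, model = "threeway",
                             method = "ols")
    observed <- threshold_and_label(statmap, p_two_tailed, connectivity)
    null <- permutation_cluster_cutoff(maps, sim$scans, sim$mask,
                                       model = "threeway",
                                       n_permutations = n_permutations,
                                       alpha = alpha,
                                       p_two_tailed = p_two_tailed,
                                       connectivity = connectivity,
                                       seed = derive_seed(study_seed, 1))
    max_obs <- if (nrow(observed$clusters)) max(observed$clusters$size) else 0L
    tibble(study = s, cutoff = null$cutoff, max_observed = max_obs,
           survived = max_obs >= null$cutoff)
  }) |> list_rbind()
}
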