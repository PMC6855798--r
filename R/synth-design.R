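#' Build a crossover scan design
#'
#' Creates the scan table for a two-group crossover study: each subject
#' belongs to one stimulation-target group (`PMN` or `PFC`) and contributes
#' four scans (stim/sham x retrieval/rest).  The order in which subjects
#' received stimulation and sham weeks is counterbalanced within group
#' (exactly half `stim_first` when `n_per_group` is even).
#'
#' @param n_per_group Number of subjects per group (>= 1).
#' @param seed Integer seed; the same seed always yields the same table.
#' @return A tibble with one row per scan and columns `subject_id`,
#'   `group`, `condition`, `task`, `order`, `scan_id`.
#' @examples
#' design <- make_design(4, seed = 1)
#' dplyr::count(design, group, order)
#' @export
make_design <- function(n_per_group, seed = 1L) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      !is.finite(n_per_group) || n_per_group < 1 ||
      n_per_group != round(n_per_group)) {
    abort("`n_per_group` must be a positive whole number.")
  }
  n_per_group <- as.integer(n_per_group)
  with_seed(seed, {
    subjects <- purrr::map(c("PMN", "PFC"), function(g) {
      offset <- if (g == "PMN") 0L else n_per_group
      orders <- sample(rep(c("stim_first", "sham_first"),
                           length.out = n_per_group))
      tibble(subject_id = offset + seq_len(n_per_group),
             group = g, order = orders)
    }) |> list_rbind()
    design <- expand_grid(subjects,
                          condition = c("stim", "sham"),
                          task = c("retrieval", "rest")) |>
      mutate(scan_id = sprintf("s%03d_%s_%s", .data$subject_id,
                               .data$condition, .data$task)) |>
      select("subject_id", "group", "condition", "task", "order", "scan_id") |>
      arrange(.data$subject_id, .data$condition, .data$task)
    design
  })
}

#' Specify planted effect sizes for the synthetic generators
#'
#' Collects the parameters of the simulated study in one validated record.
#' All connectivity parameters are on the Fisher-z scale; `tanh()` maps
#' them back to correlations, so any finite value yields `|r| < 1`.
#'
#' @param baseline_z Within-network baseline connectivity (Fisher z).
#' @param delta_3way Increment applied to within-network edges of the
#'   `affected_networks` only in the (group = PMN, condition = stim,
#'   task = retrieval) cell: the planted three-way interaction.
#' @param delta_task Increment applied to within-network edges on every
#'   retrieval scan (a planted task main effect; 0 by default).
#' @param subject_sd Between-subject random-intercept SD (Fisher z),
#'   shared across a subject's four scans.
#' @param noise_sd Marginal SD of the simulated signals; scaled per scan
#'   by a log-normal factor with log-SD `tsnr_lnsd`, which is recorded as
#'   the tSNR covariate.
#' @param behavior_slope Context-recollection change per unit of the
#'   subject's connectivity interaction effect.
#' @param behavior_sd SD of behavioural noise around that line.
#' @param tsnr_lnsd Log-SD of the per-scan noise-scale multiplier.
#' @param affected_networks Networks whose within-network edges carry the
#'   planted interaction (default `"PMN"`).
#' @return An `effect_spec` object (a validated list).
#' @examples
#' effect_spec(delta_3way = 0)  # a null study
#' @export
effect_spec <- function(baseline_z = 0.2, delta_3way = 0.25, delta_task = 0,
                        subject_sd = 0.1, noise_sd = 1, behavior_slope = 0.5,
                        behavior_sd = 0.05, tsnr_lnsd = 0.1,
                        affected_networks = "PMN") {
  assert_scalar_number(baseline_z, "baseline_z")
  assert_scalar_number(delta_3way, "delta_3way")
  assert_scalar_number(delta_task, "delta_task")
  for (nm in c("subject_sd", "noise_sd", "behavior_sd", "tsnr_lnsd")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  assert_scalar_number(behavior_slope, "behavior_slope")
  if (!is.finite(tanh(baseline_z + delta_3way + delta_task))) {
    abort("effect sizes imply |r| >= 1.")
  }
  structure(
    list(baseline_z = baseline_z, delta_3way = delta_3way,
         delta_task = delta_task, subject_sd = subject_sd,
         noise_sd = noise_sd, behavior_slope = behavior_slope,
         behavior_sd = behavior_sd, tsnr_lnsd = tsnr_lnsd,
         affected_networks = affected_networks),
    class = "effect_spec"
  )
}

#' @export
print.effect_spec <- function(x, ...) {
  cat("<effect_spec>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

# Is this scan in the planted three-way cell?
in_planted_cell <- function(group, condition, task) {
  group == "PMN" & condition == "stim" & task == "retrieval"
}

# Per-subject random intercepts and per-scan noise scales + tSNR covariate,
# drawn once per simulated study.
draw_scan_nuisance <- function(design, effects) {
  subjects <- unique(design$subject_id)
  u <- setNames(rnorm(length(subjects), 0, effects$subject_sd),
                as.character(subjects))
  scale <- effects$noise_sd * exp(rnorm(nrow(design), 0, effects$tsnr_lnsd))
  list(subject_intercept = u,
       noise_scale = scale,
       tsnr = 100 / scale)
}
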