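#' Score one assessment's memory-task trials
#'
#' Item recognition is the proportion of all test trials answered
#' correctly (hits plus correct rejections).  Context recollection is
#' the proportion of correct context choices (one of six options) among
#' items correctly recognised as old with high confidence; it is
#' undefined (`NA`) when there are no high-confidence hits.
#'
#' @param trials Trial tibble with columns `is_old`, `response`
#'   (`"old"`/`"new"`), `confidence` (`"high"`/`"low"`), `true_context`,
#'   `context_choice`.
#' @return One-row tibble: `n_trials`, `item_recognition`,
#'   `n_high_conf_hits`, `context_recollection`.
#' @export
score_memory <- function(trials) {
  trials <- as_tibble(trials)
  if (!nrow(trials)) abort("`trials` is empty.")
  ctx <- trials$context_choice[!is.na(trials$context_choice)]
  if (length(ctx) && any(ctx < 1 | ctx > 6)) {
    abort("context choices must be among 6 options.")
  }
  correct_item <- (trials$is_old & trials$response == "old") |
    (!trials$is_old & trials$response == "new")
  hc_hits <- trials$is_old & trials$response == "old" &
    trials$confidence == "high"
  n_hc <- sum(hc_hits)
  ctx_correct <- trials$true_context == trials$context_choice
  tibble(
    n_trials = nrow(trials),
    item_recognition = mean(correct_item),
    n_high_conf_hits = n_hc,
    context_recollection = if (n_hc == 0) NA_real_
                           else mean(ctx_correct[hc_hits]))
}

#' Paired stimulation-effect test on behaviour
#'
#' Paired t-test of an assessment contrast across subjects.  The
#' post-stimulation versus post-sham comparison is directional
#' (one-tailed in the improvement direction) by default, matching the
#' a-priori hypothesis; baseline checks are two-tailed.  Subjects with
#' an undefined score on either side are dropped pairwise with a
#' message.
#'
#' @param scores Score tibble (from [score_memory()] rows) with
#'   `subject_id`, `assessment` and the score column.
#' @param score Which score to contrast.
#' @param comparison `"post_stim_vs_post_sham"` or `"pre_vs_pre"`.
#' @param one_tailed Directional test?  Defaults to `TRUE` for the post
#'   contrast and is forced two-tailed for the baseline check.
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `df`, `p_value`, `n_pairs`, `alternative`.
#' @export
behavior_contrast <- function(scores,
                              score = c("context_recollection", "item_recognition"),
                              comparison = c("post_stim_vs_post_sham", "pre_vs_pre"),
                              one_tailed = NULL) {
  score <- match.arg(score)
  comparison <- match.arg(comparison)
  sides <- if (comparison == "post_stim_vs_post_sham") {
    c("post_stim", "post_sham")
  } else {
    c("pre_stim", "pre_sham")
  }
  one_tailed <- one_tailed %||% (comparison == "post_stim_vs_post_sham")
  wide <- scores |>
    filter(.data$assessment %in% sides) |>
    select("subject_id", "assessment", all_of(score)) |>
    pivot_wider(names_from = "assessment", values_from = all_of(score))
  ok <- complete.cases(wide[, sides])
  if (any(!ok)) {
    inform(sprintf("%d subject(s) dropped pairwise (undefined score).",
                   sum(!ok)))
  }
  wide <- wide[ok, ]
  if (nrow(wide) < 3) abort("need >= 3 complete pairs.")
  diffs <- wide[[sides[1]]] - wide[[sides[2]]]
  alt <- if (one_tailed) "greater" else "two.sided"
  if (sd(diffs) == 0) {
    if (any(diffs != 0)) {
      abort("zero-variance nonzero differences: t undefined.")
    }
    # identical vectors: t = 0 by convention
    return(tibble(estimate = 0, statistic = 0, df = nrow(wide) - 1,
                  p_value = if (one_tailed) 0.5 else 1,
                  n_pairs = nrow(wide), alternative = alt))
  }
  ht <- t.test(diffs, alternative = alt)
  tibble(estimate = mean(diffs), statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         n_pairs = nrow(wide), alternative = alt)
}

#' Per-subject connectivity interaction effect
#'
#' The task-dependent stimulation effect on a cluster's mean
#' connectivity: `(stim_retrieval - sham_retrieval) - (stim_rest -
#' sham_rest)` on the Fisher-z scale, one value per subject.  Each
#' subject must contribute all four scans.
#'
#' @param values Tibble with `subject_id`, `condition`, `task`, `value`
#'   (one row per scan).
#' @return Tibble: `subject_id`, `interaction_effect`.
#' @export
interaction_effect_per_subject <- function(values) {
  values <- as_tibble(values)
  cells <- values |>
    group_by(.data$subject_id) |>
    summarise(n_cells = n_distinct(paste(.data$condition, .data$task)),
              n = n(), .groups = "drop")
  if (any(cells$n_cells < 4 | cells$n < 4)) {
    bad <- cells$subject_id[cells$n_cells < 4 | cells$n < 4]
    abort(paste0("missing condition x task cells for subject(s): ",
                 paste(bad, collapse = ", ")))
  }
  values |>
    mutate(sign = ifelse(.data$condition == "stim", 1, -1) *
             ifelse(.data$task == "retrieval", 1, -1)) |>
    group_by(.data$subject_id) |>
    summarise(interaction_effect = sum(.data$sign * .data$value) /
                (n() / 4), .groups = "drop")
}

#' Robust brain-behaviour regression
#'
#' Huber M-estimation (IRLS, tuning constant 1.345 by default) of the
#' per-subject memory change on the per-subject connectivity interaction
#' effect plus an optional tSNR covariate.  Inference on the
#' connectivity coefficient is a Wald-type robust F (the squared robust
#' t referred to `F(1, n - k)`), and `r_squared` is the squared
#' correlation between fitted and observed values.
#'
#' @param data Tibble with columns `interaction_effect`,
#'   `memory_change` and optionally `tsnr` (n >= 5 subjects).
#' @param psi `"huber"` (default) or `"bisquare"`.
#' @param k_huber Huber tuning constant.
#' @param max_iter IRLS iteration cap.
#' @return A `robust_fit`: coefficient tibble, robust F for the
#'   connectivity term with `(1, n - k)` df, `r_squared`, `n`,
#'   `converged`.
#' @export
robust_brain_behavior <- function(data, psi = c("huber", "bisquare"),
                                  k_huber = 1.345, max_iter = 100) {
  psi <- match.arg(psi)
  data <- as_tibble(data)
  needed <- c("interaction_effect", "memory_change")
  missing <- setdiff(needed, names(data))
  if (length(missing)) {
    abort(paste0("data lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 5) abort("need >= 5 subjects.")
  use_tsnr <- "tsnr" %in% names(data)
  if (use_tsnr && sd(data$tsnr) == 0) {
    warn("tSNR covariate is constant; dropped.")
    use_tsnr <- FALSE
  }
  form <- if (use_tsnr) memory_change ~ interaction_effect + tsnr
          else memory_change ~ interaction_effect
  fit <- if (psi == "huber") {
    MASS::rlm(form, data = data, psi = MASS::psi.huber, k = k_huber,
              maxit = max_iter, acc = 1e-8)
  } else {
    MASS::rlm(form, data = data, psi = MASS::psi.bisquare,
              maxit = max_iter, acc = 1e-8)
  }
  if (!fit$converged) warn("IRLS did not converge within `max_iter`.")
  ct <- coef(summary(fit))
  n <- nrow(data)
  k <- nrow(ct)
  t_conn <- unname(ct["interaction_effect", "t value"])
  f_stat <- t_conn^2
  df2 <- n - k
  coef_tbl <- tibble(term = rownames(ct), estimate = unname(ct[, "Value"]),
                     se = unname(ct[, "Std. Error"]),
                     statistic = unname(ct[, "t value"]))
  structure(
    list(coefficients = coef_tbl,
         slope = unname(coef(fit)["interaction_effect"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         f_statistic = unname(f_stat), df = c(1L, df2),
         p_value = unname(pf(f_stat, 1, df2, lower.tail = FALSE)),
         r_squared = cor(fitted(fit), data$memory_change)^2,
         n = n, converged = fit$converged, psi = psi, fit = fit),
    class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  cat(sprintf("<robust_fit> n = %d, slope = %.4g, robust F(%d, %d) = %.3g, p = %.3g, r^2 = %.3g\n",
              x$n, x$slope, x$df[1], x$df[2], x$f_statistic, x$p_value,
              x$r_squared))
  invisible(x)
}

#' @rdname robust_brain_behavior
#' @param x A `robust_fit`.
#' @param ... Unused.
#' @method tidy robust_fit
#' @export
tidy.robust_fit <- function(x, ...) x$coefficients

#' @rdname robust_brain_behavior
#' @method glance robust_fit
#' @export
glance.robust_fit <- function(x, ...) {
  tibble(n = x$n, slope = x$slope, f_statistic = x$f_statistic,
         df1 = x$df[1], df2 = x$df[2], p_value = x$p_value,
         r_squared = x$r_squared, converged = x$converged, psi = x$psi)
}
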