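# Mixed-effects contrasts on connectivity summaries.
#
# Factors are coded as +/- 0.5 sum-to-zero contrasts (stim, retrieval and
# the PMN-targeted group at +0.5), so the three-way interaction beta is
# the difference-of-differences-of-differences on the Fisher-z scale and
# directly comparable to the planted generator increment.

lme_term_names <- c(
  "(Intercept)" = "intercept", "cond_c" = "condition", "task_c" = "task",
  "group_c" = "group", "tsnr_c" = "tsnr", "order_c" = "order",
  "cond_c:task_c" = "condition:task", "cond_c:group_c" = "condition:group",
  "task_c:group_c" = "task:group",
  "cond_c:task_c:group_c" = "condition:task:group",
  "cond_c:order_c" = "condition:order")

code_lme_factors <- function(table) {
  out <- mutate(
    as_tibble(table),
    cond_c = ifelse(.data$condition == "stim", 0.5, -0.5),
    task_c = ifelse(.data$task == "retrieval", 0.5, -0.5))
  if ("group" %in% names(table)) {
    out$group_c <- ifelse(table$group == "PMN", 0.5, -0.5)
  }
  if ("order" %in% names(table)) {
    out$order_c <- ifelse(table$order == "stim_first", 0.5, -0.5)
  }
  if ("tsnr" %in% names(table)) {
    out$tsnr_c <- table$tsnr - mean(table$tsnr)
  }
  out
}

#' Fit the connectivity mixed-effects model
#'
#' REML linear mixed model with a per-subject random intercept on a
#' long-format connectivity table.  The `threeway` model crosses
#' stimulation condition, task and group (all main effects, all two-way
#' interactions and the three-way interaction, following the hierarchy
#' principle) plus a mean-centred tSNR covariate; the `twoway` model
#' drops group (fit it on one group's rows).  `include_order = TRUE` adds
#' the counterbalancing order main effect and its interaction with
#' condition as a control analysis.  Denominator degrees of freedom use
#' the Satterthwaite approximation by default.
#'
#' @param table Long tibble with columns `subject_id`, `condition`,
#'   `task`, `value`, plus `group` (threeway), and optionally `tsnr`,
#'   `order`.
#' @param model `"threeway"` or `"twoway"`.
#' @param include_order Add order terms?
#' @param df_method `"satterthwaite"` or `"residual"` (fallback).
#' @param use_tsnr Include the tSNR covariate when present?  A constant
#'   covariate is dropped with a message.
#' @param fixed_structure `"hierarchical"` (default: all lower-order
#'   terms accompany the interaction) or `"mains_only"` (main effects
#'   plus the highest interaction, no two-way terms).
#' @return An `lme_result`: tidy term table plus variance components,
#'   `n_obs`, convergence/singularity flags and the name of the
#'   interaction term of interest.
#' @examples
#' sim <- simulate_roi_timeseries(make_design(4), synthetic_atlas(),
#'                                effect_spec(), n_timepoints = 60, seed = 2)
#' mats <- lapply(sim$series, connectivity_matrix)
#' tab <- network_connectivity_table(mats, sim$scans, synthetic_atlas())
#' fit <- fit_lme(dplyr::filter(tab, network == "PMN"))
#' tidy(fit)
#' @export
fit_lme <- function(table, model = c("threeway", "twoway"),
                    include_order = FALSE,
                    df_method = c("satterthwaite", "residual"),
                    use_tsnr = TRUE,
                    fixed_structure = c("hierarchical", "mains_only")) {
  model <- match.arg(model)
  df_method <- match.arg(df_method)
  fixed_structure <- match.arg(fixed_structure)
  table <- as_tibble(table)
  needed <- c("subject_id", "condition", "task", "value",
              if (model == "threeway") "group",
              if (include_order) "order")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    abort(paste0("table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (min(table(table$subject_id)) < 2) {
    abort("every subject needs >= 2 rows.")
  }
  dat <- code_lme_factors(table)
  rhs <- if (fixed_structure == "hierarchical") {
    if (model == "threeway") "cond_c * task_c * group_c" else "cond_c * task_c"
  } else {
    if (model == "threeway") {
      "cond_c + task_c + group_c + cond_c:task_c:group_c"
    } else {
      "cond_c + task_c + cond_c:task_c"
    }
  }
  has_tsnr <- use_tsnr && "tsnr" %in% names(table)
  if (has_tsnr && sd(dat$tsnr_c) == 0) {
    inform("tSNR covariate is constant; dropped from the model.")
    has_tsnr <- FALSE
  }
  if (has_tsnr) rhs <- paste(rhs, "+ tsnr_c")
  if (include_order) rhs <- paste(rhs, "+ order_c + cond_c:order_c")
  form <- stats::as.formula(paste("value ~", rhs, "+ (1 | subject_id)"))

  messages <- character()
  fit <- withCallingHandlers(
    lmerTest::lmer(form, data = dat, REML = TRUE),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  singular <- lme4::isSingular(fit)
  converged <- !any(grepl("failed to converge", messages, ignore.case = TRUE))

  ct <- coef(summary(fit, ddf = if (df_method == "satterthwaite")
                                  "Satterthwaite" else "lme4"))
  terms <- tibble(
    term = unname(lme_term_names[rownames(ct)] %||% rownames(ct)),
    estimate = unname(ct[, "Estimate"]), se = unname(ct[, "Std. Error"]),
    df = if (df_method == "satterthwaite") unname(ct[, "df"])
         else nrow(dat) - nrow(ct),
    statistic = unname(ct[, "t value"]))
  terms$term[is.na(terms$term)] <- rownames(ct)[is.na(terms$term)]
  terms$p_value <- 2 * pt(-abs(terms$statistic), terms$df)

  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(terms = terms,
         subject_variance = vc$vcov[vc$grp == "subject_id"],
         residual_variance = vc$vcov[vc$grp == "Residual"],
         n_obs = nrow(dat), model = model, df_method = df_method,
         converged = converged, singular = singular,
         interaction_term = if (model == "threeway")
           "condition:task:group" else "condition:task",
         fit = fit),
    class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> %s model, %d obs, %s df%s%s\n",
              x$model, x$n_obs, x$df_method,
              if (x$singular) ", singular random effect" else "",
              if (!x$converged) ", NOT converged" else ""))
  print(x$terms)
  invisible(x)
}

#' @rdname fit_lme
#' @param x An `lme_result`.
#' @param ... Unused.
#' @method tidy lme_result
#' @export
tidy.lme_result <- function(x, ...) x$terms

#' @rdname fit_lme
#' @method glance lme_result
#' @export
glance.lme_result <- function(x, ...) {
  it <- x$terms[x$terms$term == x$interaction_term, ]
  tibble(n_obs = x$n_obs, model = x$model,
         subject_variance = x$subject_variance,
         residual_variance = x$residual_variance,
         interaction_estimate = it$estimate, interaction_statistic = it$statistic,
         interaction_df = it$df, interaction_p = it$p_value,
         converged = x$converged, singular = x$singular)
}

# Pull one term's row from an lme_result.
lme_term <- function(result, term = result$interaction_term) {
  row <- result$terms[result$terms$term == term, ]
  if (!nrow(row)) abort(sprintf("term '%s' not in the fit.", term))
  row
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH adjustment: adjusted `p(i) = min over j >= i of
#' m * p(j) / j`, capped at 1; a hypothesis is rejected when its adjusted
#' p-value is at most `q`.
#'
#' @param pvalues Numeric p-values in `[0, 1]` (no `NA`).
#' @param q FDR level (default 0.05).
#' @return Tibble with `p_value`, `p_adj`, `reject`.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.2))
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (anyNA(pvalues) || !is.numeric(pvalues)) {
    abort("`pvalues` must be numeric without NA.")
  }
  if (any(pvalues < 0 | pvalues > 1)) abort("p-values must be in [0, 1].")
  adj <- p.adjust(pvalues, method = "BH")
  tibble(p_value = as.numeric(pvalues), p_adj = adj, reject = adj <= q)
}

#' Edge-level interaction tests with FDR correction
#'
#' Fits [fit_lme()] to every within-network region pair's Fisher-z values
#' and adjusts the interaction-term p-values with Benjamini-Hochberg,
#' separately per network.  Betas are signed so that positive means a
#' larger stim-minus-sham difference during retrieval than rest for the
#' PMN-targeted group.  Non-convergent edges are flagged and excluded
#' from the FDR family with a warning.
#'
#' @param edge_table Output of [edge_connectivity_table()].
#' @param model,include_order,use_tsnr Passed to [fit_lme()].
#' @param q FDR level.
#' @return Tibble per edge: `network`, `region_a`, `region_b`,
#'   `estimate`, `se`, `statistic`, `df`, `p_value`, `p_adj`,
#'   `significant`, `converged`.
#' @export
edge_interaction_tests <- function(edge_table, model = "threeway",
                                   include_order = FALSE, use_tsnr = TRUE,
                                   q = 0.05) {
  res <- edge_table |>
    group_by(.data$network, .data$region_a, .data$region_b) |>
    group_modify(function(df, key) {
      fit <- fit_lme(df, model = model, include_order = include_order,
                     use_tsnr = use_tsnr)
      row <- lme_term(fit)
      tibble(estimate = row$estimate, se = row$se, statistic = row$statistic,
             df = row$df, p_value = row$p_value, n_obs = fit$n_obs,
             converged = fit$converged)
    }) |>
    ungroup()
  if (any(!res$converged)) {
    warn(sprintf("%d edge fit(s) did not converge; excluded from FDR.",
                 sum(!res$converged)))
  }
  res |>
    group_by(.data$network) |>
    mutate(p_adj = {
      ok <- .data$converged
      out <- rep(NA_real_, length(ok))
      out[ok] <- fdr_bh(.data$p_value[ok], q)$p_adj
      out
    },
    significant = !is.na(.data$p_adj) & .data$p_adj <= q) |>
    ungroup()
}
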