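test_that("balanced-design fixed effects match the OLS oracle", {
  tab <- direct_network_table(8, delta = 0.25, subject_sd = 0, seed = 2)
  fit <- fit_lme(tab, use_tsnr = FALSE)
  dat <- taskconn:::code_lme_factors(tab)
  ols <- lm(value ~ cond_c * task_c * group_c, data = dat)
  expect_lt(max(abs(fit$terms$estimate - unname(coef(ols)))), 1e-6)
  # the interaction beta is the difference-of-differences-of-differences
  cellmeans <- tapply(tab$value, list(tab$condition, tab$task, tab$group),
                      mean)
  dodod <- (cellmeans["stim", "retrieval", "PMN"] -
              cellmeans["sham", "retrieval", "PMN"] -
              (cellmeans["stim", "rest", "PMN"] -
                 cellmeans["sham", "rest", "PMN"])) -
    (cellmeans["stim", "retrieval", "PFC"] -
       cellmeans["sham", "retrieval", "PFC"] -
       (cellmeans["stim", "rest", "PFC"] - cellmeans["sham", "rest", "PFC"]))
  est <- fit$terms$estimate[fit$terms$term == "condition:task:group"]
  expect_lt(abs(est - dodod), 1e-8)
  expect_equal(fit$n_obs, nrow(tab))

  # in the balanced design the flat structure gives the same interaction
  flat <- fit_lme(tab, use_tsnr = FALSE, fixed_structure = "mains_only")
  expect_false(any(grepl("^condition:task$", flat$terms$term)))
  expect_equal(flat$terms$estimate[flat$terms$term == "condition:task:group"],
               est, tolerance = 1e-6)
})

test_that("statistics are invariant to subject relabelling", {
  tab <- direct_network_table(4, delta = 0.2, seed = 3)
  perm <- sample(unique(tab$subject_id))
  relabelled <- tab
  relabelled$subject_id <- perm[match(tab$subject_id, unique(tab$subject_id))]
  f1 <- fit_lme(tab)
  f2 <- fit_lme(relabelled)
  expect_equal(f1$terms$estimate, f2$terms$estimate, tolerance = 1e-8)
  expect_equal(f1$terms$statistic, f2$terms$statistic, tolerance = 1e-6)
})

test_that("a constant tSNR covariate is dropped without changing the fit", {
  tab <- direct_network_table(4, delta = 0.2, seed = 4)
  tab$tsnr <- 100
  expect_message(fit_const <- fit_lme(tab), "constant")
  fit_none <- fit_lme(tab, use_tsnr = FALSE)
  expect_equal(fit_const$terms, fit_none$terms)
})

test_that("twoway model fits one group's rows", {
  tab <- direct_network_table(6, delta = 0.3, seed = 5)
  pmn <- dplyr::filter(tab, group == "PMN")
  fit <- fit_lme(pmn, model = "twoway")
  expect_equal(fit$interaction_term, "condition:task")
  expect_equal(fit$n_obs, nrow(pmn))
  expect_true(all(c("condition", "task", "condition:task") %in%
                    fit$terms$term))
  expect_false("group" %in% fit$terms$term)
})

test_that("order control terms are available and behave as controls", {
  tab <- direct_network_table(8, delta = 0.25, seed = 6)
  fit <- fit_lme(tab, include_order = TRUE)
  expect_true(all(c("order", "condition:order") %in% fit$terms$term))
  # order carries no effect in the generator
  expect_gt(fit$terms$p_value[fit$terms$term == "order"], 0.01)
})

test_that("BH adjustment matches the hand step-up oracle", {
  res <- fdr_bh(c(0.01, 0.02, 0.2), q = 0.05)
  # hand: 0.01*3/1 = 0.03, 0.02*3/2 = 0.03, 0.2*3/3 = 0.2
  expect_equal(res$p_adj, c(0.03, 0.03, 0.2))
  expect_equal(res$reject, c(TRUE, TRUE, FALSE))

  expect_equal(fdr_bh(0.04)$reject, TRUE)
  expect_equal(fdr_bh(0.06)$reject, FALSE)
  all_eq <- fdr_bh(rep(0.001, 10))
  expect_true(all(all_eq$reject))
  expect_equal(all_eq$p_adj, rep(0.001, 10))
  # independent step-up oracle on random p-values
  set.seed(8)
  p <- runif(20)
  m <- length(p)
  ord <- order(p)
  stepup <- numeric(m)
  stepup[ord] <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  expect_equal(fdr_bh(p)$p_adj, pmin(stepup, 1))
  expect_error(fdr_bh(c(0.1, NA)), "NA")
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("edge tests localise a single planted edge", {
  atlas_edges <- tidyr::expand_grid(network = c("PMN", "ATN"),
                                    pair = 1:3)
  make_edge_table <- function(seed) {
    design <- make_design(8, seed = seed)
    withr::with_seed(seed + 500, {
      rows <- tidyr::expand_grid(
        design,
        tibble::tibble(network = rep(c("PMN", "ATN"), each = 3),
                       region_a = paste0("a", rep(1:3, 2)),
                       region_b = paste0("b", rep(1:3, 2))))
      planted <- rows$network == "PMN" & rows$region_a == "a1" &
        rows$group == "PMN" & rows$condition == "stim" &
        rows$task == "retrieval"
      rows$value <- 0.2 + 0.4 * planted + stats::rnorm(nrow(rows), 0, 0.1)
      rows$tsnr <- stats::rnorm(nrow(rows), 100, 5)
      rows
    })
  }
  hits <- vapply(1:20, function(s) {
    res <- edge_interaction_tests(make_edge_table(s))
    pmn <- dplyr::filter(res, network == "PMN")
    pmn$region_a[which.min(pmn$p_value)] == "a1"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  # planted edge significant after FDR in a typical run
  res <- edge_interaction_tests(make_edge_table(1))
  expect_true(dplyr::filter(res, network == "PMN", region_a == "a1")$significant)
  # adjusted p never below raw p
  expect_true(all(res$p_adj >= res$p_value - 1e-12))
})

test_that("duplicated scans double n_obs and shrink edge SEs", {
  tab <- direct_network_table(4, delta = 0.2, seed = 9)
  # without the (unbalanced) covariate the point estimates are exact
  fit1 <- fit_lme(tab, use_tsnr = FALSE)
  fit2 <- fit_lme(dplyr::bind_rows(tab, tab), use_tsnr = FALSE)
  expect_equal(fit2$n_obs, 2L * fit1$n_obs)
  i1 <- fit1$terms
  i2 <- fit2$terms
  expect_equal(i2$estimate[i2$term == "condition:task:group"],
               i1$estimate[i1$term == "condition:task:group"],
               tolerance = 1e-6)
  expect_lt(i2$se[i2$term == "condition:task:group"],
            i1$se[i1$term == "condition:task:group"])
})

test_that("tidy and glance expose the interaction term", {
  tab <- direct_network_table(4, delta = 0.25, seed = 10)
  fit <- fit_lme(tab)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "se", "df", "statistic", "p_value")
                  %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$interaction_estimate,
               td$estimate[td$term == "condition:task:group"])
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
  expect_true(all(td$df > 0))
})
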