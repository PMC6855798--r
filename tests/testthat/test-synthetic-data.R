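test_that("make_design builds counterbalanced crossover tables", {
  d <- make_design(16, seed = 3)
  expect_equal(length(unique(d$subject_id)), 32)
  expect_equal(nrow(d), 128)
  # every subject: 4 scans covering all condition x task cells, one group
  per_subj <- dplyr::count(d, subject_id)
  expect_true(all(per_subj$n == 4))
  cells <- dplyr::distinct(d, subject_id, condition, task)
  expect_equal(nrow(cells), 128)
  expect_true(all(tapply(d$group, d$subject_id,
                         function(g) length(unique(g))) == 1))
  # exact counterbalancing of order within each group for even n
  tab <- dplyr::count(dplyr::distinct(d, subject_id, group, order),
                      group, order)
  expect_true(all(tab$n == 8))

  expect_equal(nrow(make_design(1)), 8)
  expect_identical(make_design(4, seed = 9), make_design(4, seed = 9))
  expect_false(identical(make_design(4, seed = 9), make_design(4, seed = 10)))
  expect_error(make_design(0), "positive")
  expect_error(make_design(2.5), "whole")
})

test_that("effect_spec validates its parameters", {
  expect_s3_class(effect_spec(), "effect_spec")
  expect_error(effect_spec(subject_sd = -1), ">= 0")
  expect_error(effect_spec(noise_sd = NA), "finite")
  expect_error(effect_spec(baseline_z = Inf), "finite|\\|r\\|")
})

test_that("roi generator reproduces its generating correlation", {
  atlas <- synthetic_atlas()
  design <- make_design(1, seed = 1)[1, ]
  eff <- effect_spec(baseline_z = 0.3, delta_3way = 0, subject_sd = 0,
                     tsnr_lnsd = 0)
  sim <- simulate_roi_timeseries(design, atlas, eff, n_timepoints = 500,
                                 seed = 4)
  mat <- sim$series[[1]]
  pmn <- atlas$name[atlas$network == "PMN"]
  rs <- cor(t(mat[pmn, ]))
  mean_r <- mean(rs[upper.tri(rs)])
  # large-sample within-network correlation approaches tanh(0.3)
  expect_lt(abs(mean_r - tanh(0.3)), 0.1)
  # cross-network correlation approaches zero
  atn <- atlas$name[atlas$network == "ATN"]
  cross <- cor(t(mat[pmn, ]), t(mat[atn, ]))
  expect_lt(abs(mean(cross)), 0.1)
})

test_that("fixed seeds make every generator bit-identical", {
  design <- make_design(2, seed = 5)
  atlas <- synthetic_atlas()
  eff <- effect_spec()
  a <- simulate_roi_timeseries(design, atlas, eff, 40, seed = 11)
  b <- simulate_roi_timeseries(design, atlas, eff, 40, seed = 11)
  expect_identical(a, b)
  va <- simulate_voxel_dataset(design, c(8, 8, 8), effects = eff,
                               n_timepoints = 20, seed = 11)
  vb <- simulate_voxel_dataset(design, c(8, 8, 8), effects = eff,
                               n_timepoints = 20, seed = 11)
  expect_identical(va$series, vb$series)
  ie <- stats::setNames(rep(0.1, 4), as.character(unique(design$subject_id)))
  ba <- simulate_behavior(design, ie, eff, seed = 11)
  bb <- simulate_behavior(design, ie, eff, seed = 11)
  expect_identical(ba, bb)
  ma <- simulate_motion(design, 30, seed = 11)
  expect_identical(ma, simulate_motion(design, 30, seed = 11))
})

test_that("null roi generator gives a centred interaction contrast", {
  atlas <- synthetic_atlas()
  eff <- effect_spec(delta_3way = 0, subject_sd = 0)
  contrasts <- vapply(1:100, function(s) {
    design <- make_design(2, seed = s)
    sim <- simulate_roi_timeseries(design, atlas, eff, n_timepoints = 60,
                                   seed = 1000 + s)
    mats <- lapply(sim$series, connectivity_matrix)
    tab <- network_connectivity_table(mats, sim$scans, atlas, "PMN")
    effs <- interaction_effect_per_subject(tab)
    grp <- sim$scans$group[match(effs$subject_id, sim$scans$subject_id)]
    mean(effs$interaction_effect[grp == "PMN"]) -
      mean(effs$interaction_effect[grp == "PFC"])
  }, numeric(1))
  se <- sd(contrasts) / sqrt(length(contrasts))
  expect_lt(abs(mean(contrasts)), 2 * se + 1e-12)
})

test_that("voxel generator: one community at full mixing is perfectly coupled", {
  design <- make_design(1, seed = 1)[1, ]
  cm <- array(1L, c(4, 4, 4))
  sim <- simulate_voxel_dataset(design, c(4, 4, 4), community_map = cm,
                                effects = effect_spec(), n_timepoints = 30,
                                mixing = 1, seed = 2)
  gc_map <- global_connectedness(sim$series[[1]], sim$mask)
  expect_true(all(abs(gc_map - atanh(1 - 1e-7)) < 1e-12))
})

test_that("voxel generator: zero mixing yields independent noise", {
  design <- make_design(1, seed = 1)[1, ]
  cm <- array(rep(1:2, each = 108), c(6, 6, 6))
  sim <- simulate_voxel_dataset(design, c(6, 6, 6), community_map = cm,
                                effects = effect_spec(subject_sd = 0),
                                n_timepoints = 100, mixing = 0, seed = 3)
  gc_map <- global_connectedness(sim$series[[1]], sim$mask)
  expect_lt(abs(mean(gc_map)), 0.02)
})

test_that("voxel generator: a coupled community stands out from background", {
  design <- make_design(1, seed = 1)[1, ]
  cm <- array(0L, c(16, 16, 16))
  cm[3:6, 3:7, 3:4] <- 1L  # 40-voxel community
  hits <- vapply(1:100, function(s) {
    sim <- simulate_voxel_dataset(design, c(16, 16, 16), community_map = cm,
                                  effects = effect_spec(subject_sd = 0),
                                  n_timepoints = 60, mixing = 0.5, seed = s)
    gc_map <- global_connectedness(sim$series[[1]], sim$mask, method = "fast")
    mean(gc_map[cm == 1L]) > mean(gc_map[cm == 0L])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("community/grid shape mismatches and bad specs are rejected", {
  design <- make_design(1, seed = 1)
  expect_error(simulate_voxel_dataset(design, c(8, 8, 8),
                                      community_map = array(1L, c(4, 4, 4))),
               "dimensions")
  expect_error(simulate_roi_timeseries(design, synthetic_atlas(),
                                       effect_spec(), n_timepoints = 10),
               ">= 20")
})

test_that("behavioural generator: null coupling and guessing behave as designed", {
  design <- make_design(8, seed = 2)
  subjects <- unique(design$subject_id)
  ie <- stats::setNames(stats::rnorm(length(subjects), 0, 0.2),
                        as.character(subjects))
  # slope 0, behavioural noise 0: the generating change is exactly zero
  b0 <- simulate_behavior(design, ie,
                          effect_spec(behavior_slope = 0, behavior_sd = 0),
                          seed = 5)
  expect_true(all(b0$true_change$context_change == 0))
  wide <- tidyr::pivot_wider(
    dplyr::select(b0$scores, subject_id, assessment, context_recollection),
    names_from = assessment, values_from = context_recollection)
  expect_lt(abs(mean(wide$post_stim - wide$post_sham)), 0.1)

  # guessing generator: context recollection concentrates on 1/6
  dg <- make_design(100, seed = 3)
  ieg <- stats::setNames(rep(0, 200), as.character(unique(dg$subject_id)))
  bg <- simulate_behavior(dg, ieg,
                          effect_spec(behavior_slope = 0, behavior_sd = 0),
                          seed = 6, p_context_base = 1 / 6)
  post <- dplyr::filter(bg$scores, assessment == "post_stim")
  expect_lt(abs(mean(post$context_recollection, na.rm = TRUE) - 1 / 6), 0.02)
})

test_that("behavioural slope is recovered by the robust regression", {
  slopes <- vapply(1:100, function(s) {
    design <- make_design(16, seed = s)
    subjects <- unique(design$subject_id)
    ie <- withr::with_seed(s, stats::setNames(
      stats::rnorm(length(subjects), 0, 0.25), as.character(subjects)))
    beh <- simulate_behavior(design, ie,
                             effect_spec(behavior_slope = 0.5,
                                         behavior_sd = 0.02),
                             seed = 5000 + s)
    wide <- tidyr::pivot_wider(
      dplyr::select(beh$scores, subject_id, assessment, context_recollection),
      names_from = assessment, values_from = context_recollection)
    df <- tibble::tibble(interaction_effect = ie[as.character(wide$subject_id)],
                         memory_change = wide$post_stim - wide$post_sham)
    robust_brain_behavior(df[stats::complete.cases(df), ])$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.5), 0.1)
})
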