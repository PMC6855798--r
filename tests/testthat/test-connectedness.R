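test_that("global connectedness equals the brute-force double loop", {
  set.seed(11)
  v <- 200
  vt <- matrix(rnorm(v * 30), v, 30)
  vt[2, ] <- vt[1, ] + rnorm(30, sd = 0.1)  # a correlated pair
  vs <- series_from_matrix(vt, c(10, 5, 4))
  brute <- vapply(seq_len(v), function(i) {
    rs <- vapply(setdiff(seq_len(v), i), function(j) {
      min(max(cor(vt[i, ], vt[j, ]), -(1 - 1e-7)), 1 - 1e-7)
    }, numeric(1))
    atanh(min(max(mean(rs), -(1 - 1e-7)), 1 - 1e-7))
  }, numeric(1))
  for (method in c("matrix", "fast")) {
    gc_map <- global_connectedness(vs, method = method)
    expect_lt(max(abs(as.numeric(gc_map)[seq_len(v)] - brute)), 1e-8)
  }
})

test_that("the 3-voxel toy matches hand-computed correlations", {
  a <- c(1, 2, 3, 4); b <- c(4, 3, 2, 1); c_ <- c(1, 3, 2, 4)
  vs <- series_from_matrix(rbind(a, b, c_), c(3, 1, 1))
  gc_map <- global_connectedness(vs, method = "matrix")
  # r(a, b) = -1 (clamped to -0.9999999), r(a, c) = 0.8 by direct formula
  expect_equal(gc_map[1, 1, 1], atanh((-(1 - 1e-7) + 0.8) / 2),
               tolerance = 1e-10)
  expect_equal(gc_map[2, 1, 1], atanh((-(1 - 1e-7) + -0.8) / 2),
               tolerance = 1e-10)
  expect_equal(gc_map[3, 1, 1], atanh((0.8 - 0.8) / 2), tolerance = 1e-10)
})

test_that("identical series clamp to the maximum and degenerates error", {
  vt <- matrix(rep(sin(1:20), each = 8), 8)
  vs <- series_from_matrix(vt, c(2, 2, 2))
  gc_map <- global_connectedness(vs)
  expect_true(all(abs(gc_map - atanh(1 - 1e-7)) < 1e-12))

  # zero-variance voxels drop out with a warning
  vt2 <- rbind(matrix(rnorm(3 * 20), 3), rep(1, 20))
  vs2 <- series_from_matrix(vt2, c(4, 1, 1))
  expect_warning(gc2 <- global_connectedness(vs2), "zero-variance")
  expect_true(is.na(gc2[4, 1, 1]))
  expect_error(suppressWarnings(
    global_connectedness(series_from_matrix(matrix(1, 2, 20), c(2, 1, 1)))),
    "usable")
})

test_that("appending an independent voxel dilutes mean correlation", {
  drops <- vapply(1:100, function(s) {
    set.seed(s)
    base <- matrix(rnorm(20 * 30), 20, 30)
    shared <- rnorm(30)
    vt <- sweep(base, 2, shared, `+`)  # correlated background
    vs_small <- series_from_matrix(vt, c(20, 1, 1))
    vs_big <- series_from_matrix(rbind(vt, rnorm(30)), c(21, 1, 1))
    g1 <- global_connectedness(vs_small, method = "matrix")
    g2 <- global_connectedness(vs_big, method = "matrix")
    mean(tanh(g2[seq_len(20), 1, 1])) - mean(tanh(g1[, 1, 1]))
  }, numeric(1))
  expect_lt(mean(drops), 0)
})

test_that("voxelwise fits agree between map level and scalar level", {
  set.seed(12)
  scans <- direct_network_table(4, delta = 0, seed = 13)
  v <- 8
  Y <- matrix(rnorm(nrow(scans) * v), nrow(scans), v)
  mask <- array(TRUE, c(2, 2, 2))
  sm <- voxelwise_lme(Y, scans, mask, model = "threeway", method = "lme")
  for (i in c(1, 5)) {
    ref <- fit_lme(dplyr::mutate(scans, value = Y[, i]))
    row <- ref$terms[ref$terms$term == "condition:task:group", ]
    expect_equal(sm$t[which(mask)[i]], row$statistic, tolerance = 1e-6)
    expect_equal(sm$beta[which(mask)[i]], row$estimate, tolerance = 1e-8)
  }
  # identical maps across scans: t = 0, p = 1 everywhere (OLS path)
  Y0 <- matrix(1.3, nrow(scans), v)
  sm0 <- voxelwise_lme(Y0, scans, mask, method = "ols", use_tsnr = FALSE)
  expect_true(all(sm0$t[mask] == 0))
  expect_true(all(sm0$p[mask] == 1))
})

test_that("subject-centred OLS t closely tracks the REML t per voxel", {
  set.seed(14)
  scans <- direct_network_table(6, delta = 0, seed = 15)
  v <- 27
  u <- rnorm(12, sd = 0.3)[as.integer(factor(scans$subject_id))]
  Y <- matrix(rnorm(nrow(scans) * v, sd = 0.2), nrow(scans), v) + u
  mask <- array(TRUE, c(3, 3, 3))
  ols <- voxelwise_lme(Y, scans, mask, method = "ols")
  lme <- voxelwise_lme(Y, scans, mask, method = "lme")
  expect_gt(cor(ols$t[mask], lme$t[mask]), 0.99)
})

test_that("threshold_and_label matches the flood-fill oracle", {
  # single suprathreshold voxel
  p <- array(1, c(5, 5, 5))
  p[3, 3, 3] <- 0.01
  cs <- threshold_and_label(toy_stat_map(p))
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$size, 1)

  # corner-touching voxels: separate under 6-connectivity, merged under 26
  p2 <- array(1, c(4, 4, 4))
  p2[1, 1, 1] <- p2[2, 2, 2] <- 0.01
  expect_equal(nrow(threshold_and_label(toy_stat_map(p2), connectivity = 6)$clusters), 2)
  expect_equal(nrow(threshold_and_label(toy_stat_map(p2), connectivity = 26)$clusters), 1)

  # random volumes against the oracle, all adjacencies
  set.seed(16)
  for (conn in c(6, 18, 26)) {
    m <- array(runif(6^3) < 0.25, c(6, 6, 6))
    lab <- label_components(m, conn)
    oracle <- flood_fill_components(m, conn)
    expect_equal(max(lab), max(oracle))
    # identical partitions (labels may be permuted)
    expect_equal(length(unique(paste(lab[m], oracle[m]))), max(lab))
    expect_equal(sum(attr(lab, "sizes")), sum(m))
  }

  # empty suprathreshold set is a valid empty cluster set
  none <- threshold_and_label(toy_stat_map(array(1, c(3, 3, 3))))
  expect_equal(nrow(none$clusters), 0)
})

test_that("cluster metadata partitions the suprathreshold voxels", {
  set.seed(17)
  p <- array(runif(5^3), c(5, 5, 5))
  tmap <- array(rnorm(5^3), c(5, 5, 5))
  cs <- threshold_and_label(toy_stat_map(p, t = tmap), p_two_tailed = 0.3)
  expect_equal(sum(cs$clusters$size), sum(p < 0.3))
  expect_setequal(setdiff(unique(as.integer(cs$labels)), 0L), cs$clusters$id)
  # peak is the max |t| within each cluster
  for (i in seq_len(nrow(cs$clusters))) {
    vox <- which(cs$labels == cs$clusters$id[i])
    expect_equal(abs(cs$clusters$peak_t[i]), max(abs(tmap[vox])))
  }
})

test_that("apply_cutoff keeps clusters at or above the boundary", {
  p <- array(1, c(100, 1, 1))
  p[1:40] <- 0.01      # 40-voxel line
  p[51:87] <- 0.01     # 37-voxel line
  cs <- threshold_and_label(toy_stat_map(array(p, c(100, 1, 1))))
  expect_setequal(cs$clusters$size, c(40, 37))
  kept <- apply_cutoff(cs, 38)
  expect_equal(kept$clusters$size, 40)
  expect_identical(apply_cutoff(cs, 1)$clusters, cs$clusters)
  expect_equal(nrow(apply_cutoff(cs, 1000)$clusters), 0)
  expect_error(apply_cutoff(cs, 0), ">= 1")
})
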