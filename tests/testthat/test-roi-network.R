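test_that("sphere membership matches the brute-force lattice oracle", {
  dims <- c(16, 16, 16)
  center <- c(16, 16, 16)  # voxel (9, 9, 9) centre on a 2 mm grid
  vox <- sphere_voxels(center, 6, dims, c(2, 2, 2))
  # oracle: integer offsets with i^2 + j^2 + k^2 <= (6/2)^2
  g <- expand.grid(i = -3:3, j = -3:3, k = -3:3)
  expect_equal(nrow(vox), sum(g$i^2 + g$j^2 + g$k^2 <= 9))  # 123
  oracle <- cbind(g$i, g$j, g$k)[g$i^2 + g$j^2 + g$k^2 <= 9, ] + 9
  expect_setequal(paste(vox[, 1], vox[, 2], vox[, 3]),
                  paste(oracle[, 1], oracle[, 2], oracle[, 3]))

  # translation by one full voxel translates the set
  vox2 <- sphere_voxels(center + c(2, 0, 0), 6, dims, c(2, 2, 2))
  expect_setequal(paste(vox2[, 1] - 1, vox2[, 2], vox2[, 3]),
                  paste(vox[, 1], vox[, 2], vox[, 3]))

  # radius below half a voxel: the single nearest centre
  tiny <- sphere_voxels(c(15.4, 16, 16), 0.5, dims, c(2, 2, 2))
  expect_equal(nrow(tiny), 1)
  expect_equal(unname(tiny[1, ]), c(9L, 9L, 9L))

  expect_error(sphere_voxels(c(200, 0, 0), 6, dims, c(2, 2, 2),
                             region = "pmr"), "pmr")
  mask <- array(FALSE, dims)
  expect_error(sphere_voxels(center, 6, dims, c(2, 2, 2), mask = mask,
                             region = "prec"), "prec")
})

test_that("mean time series extraction equals direct averaging", {
  set.seed(5)
  vt <- matrix(rnorm(27 * 10), 27, 10)
  vs <- series_from_matrix(vt, c(3, 3, 3))
  one <- extract_mean_timeseries(vs, matrix(c(2, 3, 1), 1))
  lin <- 2 + (3 - 1) * 3 + (1 - 1) * 9
  expect_equal(one, vt[lin, ])

  # mirrored series cancel
  vt2 <- rbind(vt[1, ], -vt[1, ])
  vs2 <- series_from_matrix(vt2, c(2, 1, 1))
  expect_equal(extract_mean_timeseries(vs2, rbind(c(1, 1, 1), c(2, 1, 1))),
               rep(0, 10))

  vox <- rbind(c(1, 1, 1), c(3, 2, 1), c(2, 2, 2), c(1, 3, 3), c(3, 3, 3))
  lin5 <- vox[, 1] + (vox[, 2] - 1) * 3 + (vox[, 3] - 1) * 9
  expect_lt(max(abs(extract_mean_timeseries(vs, vox) - colMeans(vt[lin5, ]))),
            1e-12)
})

test_that("connectivity matrices match the pairwise correlation oracle", {
  t_idx <- seq(0, 2 * pi, length.out = 41)[-41]
  sc <- rbind(sin(t_idx), cos(t_idx))
  rownames(sc) <- c("s", "c")
  z <- connectivity_matrix(sc)
  expect_lt(abs(z["s", "c"]), 1e-10)  # orthogonal over whole periods

  set.seed(6)
  rs <- matrix(rnorm(4 * 50), 4, dimnames = list(paste0("r", 1:4), NULL))
  z4 <- connectivity_matrix(rs)
  oracle <- atanh(cor(t(rs)))
  diag(oracle) <- NA
  expect_lt(max(abs(z4 - oracle), na.rm = TRUE), 1e-12)
  expect_identical(unclass(z4), t(unclass(z4)))
  expect_true(all(is.na(diag(z4))))

  # a duplicated region hits the clamp
  dup <- rbind(a = rs[1, ], b = rs[1, ])
  expect_equal(connectivity_matrix(dup)["a", "b"], atanh(1 - 1e-7))

  flat <- rbind(x = rep(1, 50), y = rnorm(50))
  expect_error(connectivity_matrix(flat), "x")
  expect_error(connectivity_matrix(rs[, 1:2]), ">= 3")
})

test_that("network summaries are pair means and order-invariant", {
  z <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(z) <- NA
  class(z) <- c("conn_matrix", class(z))
  expect_equal(network_interconnectivity(z, letters[1:4]), 0.3)

  set.seed(7)
  rs <- matrix(rnorm(5 * 60), 5, dimnames = list(paste0("r", 1:5), NULL))
  zm <- connectivity_matrix(rs)
  members <- paste0("r", 1:5)
  pairs <- utils::combn(5, 2)
  brute <- mean(zm[cbind(pairs[1, ], pairs[2, ])])
  expect_lt(abs(network_interconnectivity(zm, members) - brute), 1e-12)
  # invariant to member ordering
  expect_equal(network_interconnectivity(zm, rev(members)),
               network_interconnectivity(zm, members))
  # member-average of region means equals the network mean
  rm_all <- vapply(members, function(r) {
    region_mean_connectivity(zm, r, members)
  }, numeric(1))
  expect_lt(abs(mean(rm_all) - network_interconnectivity(zm, members)), 1e-12)

  z3 <- matrix(NA_real_, 3, 3, dimnames = list(c("t", "u", "v"), c("t", "u", "v")))
  z3["t", "u"] <- z3["u", "t"] <- 0.2
  z3["t", "v"] <- z3["v", "t"] <- 0.4
  z3["u", "v"] <- z3["v", "u"] <- 0.9
  class(z3) <- c("conn_matrix", class(z3))
  expect_equal(region_mean_connectivity(z3, "t", c("t", "u", "v")), 0.3)
  expect_error(network_interconnectivity(zm, "r1"), ">= 2")
})

test_that("stimulation-target selection respects the stated tie-breaks", {
  map <- array(0, c(8, 8, 8))
  map[4, 4, 4] <- 2
  mask <- array(TRUE, c(8, 8, 8))
  hit <- select_stimulation_target(map, mask, anchor_mm = c(0, 0, 0))
  expect_equal(c(hit$x, hit$y, hit$z), c(4, 4, 4))
  expect_equal(hit$value, 2)
  # two equal maxima: the one nearer the anchor wins
  map2 <- array(0, c(8, 8, 8))
  map2[2, 1, 1] <- 1   # 2 mm from anchor at voxel (1,1,1) origin 0
  map2[7, 1, 1] <- 1   # 12 mm away
  hit2 <- select_stimulation_target(map2, mask, anchor_mm = c(0, 0, 0))
  expect_equal(hit2$x, 2)
  expect_equal(hit2$distance_mm, 2)
  # planted peak: distance follows the euclidean formula
  map3 <- array(0, c(8, 8, 8))
  map3[5, 6, 7] <- 3
  hit3 <- select_stimulation_target(map3, mask, anchor_mm = c(1, 1, 1))
  expect_lt(abs(hit3$distance_mm -
                  sqrt(sum((c(8, 10, 12) - c(1, 1, 1))^2))), 1e-9)
  expect_error(select_stimulation_target(map3, array(FALSE, c(8, 8, 8)),
                                         c(0, 0, 0)), "empty")
})

test_that("roi extraction recovers the planted within/between contrast", {
  atlas <- synthetic_atlas()
  hits <- vapply(1:20, function(s) {
    design <- make_design(1, seed = s)[1, ]
    sim <- simulate_roi_timeseries(design, atlas,
                                   effect_spec(baseline_z = 0.2,
                                               subject_sd = 0),
                                   n_timepoints = 100, seed = 100 + s)
    zm <- connectivity_matrix(sim$series[[1]])
    pmn <- atlas$name[atlas$network == "PMN"]
    atn <- atlas$name[atlas$network == "ATN"]
    within <- (network_interconnectivity(zm, pmn) +
                 network_interconnectivity(zm, atn)) / 2
    between <- mean(zm[pmn, atn])
    within > between
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
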