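test_that("random_downsample honours counts, determinism and bounds", {
  cl <- uniform_cube_cloud(10)
  expect_equal(random_downsample(cl, 1.0), seq_len(10))
  expect_length(random_downsample(cl, 0.5, seed = 3), 5)
  expect_equal(random_downsample(cl, 0.5, seed = 3),
               random_downsample(cl, 0.5, seed = 3))
  expect_error(random_downsample(cl, 0), "ratio")
  expect_error(random_downsample(cl, 1.2), "ratio")
})

test_that("farthest_point_sample matches the hand-worked 1-D case", {
  pts <- cbind(c(0, 1, 2, 3, 10), 0, 0)
  expect_equal(farthest_point_sample(pts, 3, start = 1), c(1L, 5L, 4L))
  expect_equal(farthest_point_sample(pts, 1, start = 2), 2L)
  perm <- farthest_point_sample(pts, 5, start = 1)
  expect_setequal(perm, 1:5)
  expect_error(farthest_point_sample(pts, 6), "m")
  expect_error(farthest_point_sample(pts, 0), "m")
})

test_that("farthest_point_sample agrees with the brute-force oracle", {
  for (case in 1:60) {
    withr::with_seed(case, {
      m_pts <- sample(3:64, 1)
      coords <- matrix(runif(3 * m_pts), ncol = 3)
      m <- sample(seq_len(m_pts), 1)
      start <- sample(seq_len(m_pts), 1)
      expect_identical(farthest_point_sample(coords, m, start = start),
                       fps_oracle(coords, m, start))
    })
  }
})

test_that("voxel occupancy statistics follow the CV definitions", {
  # regular lattice, spacing > edge: every occupied voxel holds one point
  vs <- voxel_occupancy_stats(lattice_cloud(3, 0.1), voxel_edge = 0.05)
  expect_equal(vs$occupied_count, 27)
  expect_equal(vs$sd_occupancy, 0)
  expect_equal(vs$cv_v, 0)
  expect_equal(vs$w_v, 1)

  # 4 points: 3 in one voxel, 1 in another -> mu=2, sigma=1, CV=0.5, w=2/3
  cl <- point_cloud(rbind(c(0.01, 0.01, 0.01), c(0.02, 0.01, 0.01),
                          c(0.01, 0.02, 0.01), c(0.30, 0.01, 0.01)))
  vs <- voxel_occupancy_stats(cl, voxel_edge = 0.05)
  expect_equal(vs$mean_occupancy, 2)
  expect_equal(vs$sd_occupancy, 1)
  expect_equal(vs$cv_v, 0.5)
  expect_equal(vs$w_v, 2 / 3)

  vs <- voxel_occupancy_stats(point_cloud(matrix(c(1, 2, 3), 1)), 0.05)
  expect_equal(vs$occupied_count, 1)
  expect_equal(vs$w_v, 1)
})

test_that("knn density statistics match the brute-force oracle", {
  # two clusters of different spacing
  withr::with_seed(7, {
    a <- matrix(runif(60, 0, 0.01), ncol = 3)
    b <- matrix(runif(60, 0, 0.05), ncol = 3) + 2
  })
  cl <- point_cloud(rbind(a, b))
  ds <- knn_density_stats(cl, k = 3, cv_v = 0.5)
  rho <- knn_density_oracle(cloud_coords(cl), 3)
  expect_lt(max(abs(ds$rho - rho) / rho), 1e-12)
  expect_lt(abs(ds$cv_d - cv_oracle(rho)), 1e-12)
  expect_equal(ds$w_d, ds$cv_d / (0.5 + ds$cv_d))

  # the reciprocal density reading matches its own direct oracle
  ds_r <- knn_density_stats(cl, k = 3, cv_v = 0.5, reciprocal = TRUE)
  expect_lt(abs(ds_r$cv_d - cv_oracle(1 / rho)), 1e-12)

  # interior of a periodic-like lattice: near-identical densities
  ds_l <- knn_density_stats(lattice_cloud(6, 0.02), k = 6, cv_v = 0.5)
  expect_lt(ds_l$cv_d, 0.35)
  expect_error(knn_density_stats(point_cloud(matrix(1, 1, 3)), 5), "two points")
})

test_that("joint complexity diagnostic is the stated weighted sum", {
  expect_equal(joint_complexity(0.7, 0.3, 1), 0.7)
  expect_equal(joint_complexity(0.7, 0.3, 0), 0.3)
  expect_equal(joint_complexity(0.4, 0.8, 0.25), 0.7)
})

test_that("dmss_ratio applies the weight rule and the overall clamp", {
  p <- dmss_params()
  r <- dmss_ratio(w_v = 1, w_d = 0, p)
  expect_equal(r$r_fps, 0.5)
  expect_equal(r$overall_ratio, 0.05)
  expect_false(r$clamped)

  # CVv = CVd = 0.5, lambda = 0.5, r_base = 0.5
  r <- dmss_ratio(w_v = 2 / 3, w_d = 1 / 2, p)
  expect_equal(r$r_fps, 0.5 * (2 / 3 + 0.25), tolerance = 1e-12)
  expect_equal(r$overall_ratio, 0.1 * 0.5 * (2 / 3 + 0.25), tolerance = 1e-12)

  # clamp activation: raw overall 0.18 -> 0.08
  r <- dmss_ratio(w_v = 1, w_d = 1, dmss_params(r_base = 0.9, lambda_weight = 1))
  expect_equal(r$raw_overall, 0.18, tolerance = 1e-12)
  expect_equal(r$overall_ratio, 0.08)
  expect_true(r$clamped)

  # monotone nondecreasing in CVd at fixed CVv; decreasing in CVv via w_v
  grid_cvd <- seq(0, 2, by = 0.1)
  overall_d <- vapply(grid_cvd, function(cvd) {
    dmss_ratio(1 / (1 + 0.5), cvd / (0.5 + cvd), p)$overall_ratio
  }, numeric(1))
  expect_true(all(diff(overall_d) >= -1e-12))
  wv_grid <- 1 / (1 + seq(0, 2, by = 0.1))
  overall_v <- vapply(wv_grid, function(wv) dmss_ratio(wv, 0.3, p)$raw_overall,
                      numeric(1))
  expect_true(all(diff(overall_v) <= 1e-12))
})

test_that("dmss_sample composes the stages and respects the clamp", {
  cl <- uniform_cube_cloud(1000, seed = 5)
  res <- dmss_sample(cl, dmss_params(seed = 2))
  expect_length(res$stage1_indices, 100)
  expect_true(all(res$final_indices %in% res$stage1_indices))
  expect_gte(length(res$final_indices), 20)
  expect_lte(length(res$final_indices), 80)
  res2 <- dmss_sample(cl, dmss_params(seed = 2))
  expect_identical(res$final_indices, res2$final_indices)
  td <- tidy(res)
  expect_equal(td$n_final, length(res$final_indices))
  expect_equal(td$overall_ratio, td$n_final / 1000)
})

test_that("sub-voxel density contrast raises the adaptive ratio", {
  ratios <- vapply(1:10, function(s) {
    u <- dmss_sample(uniform_cube_cloud(3000, seed = s),
                     dmss_params(seed = s))$overall_ratio
    c <- dmss_sample(clumped_cube_cloud(3000, seed = s),
                     dmss_params(seed = s))$overall_ratio
    c - u
  }, numeric(1))
  expect_gte(median(ratios), 0)
})

test_that("FPS spreads points more evenly than random sampling", {
  cl <- generate_plant(plant_spec(stage = 6, seed = 3, points_per_area = 1.5e4))
  coords <- cloud_coords(cl)
  wins <- vapply(1:20, function(s) {
    idx_f <- farthest_point_sample(coords, 60, seed = s)
    idx_r <- random_downsample(cl, 60 / nrow(cl), seed = s)
    min_f <- min(dist(coords[idx_f, ]))
    min_r <- min(dist(coords[idx_r, ]))
    min_f - min_r
  }, numeric(1))
  expect_gt(median(wins), 0)
})
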