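make_cube_surface <- function(side = 0.1, spacing = 0.005) {
  s <- seq(0, side, by = spacing)
  g <- expand.grid(a = s, b = s)
  faces <- rbind(
    cbind(g$a, g$b, 0), cbind(g$a, g$b, side),
    cbind(g$a, 0, g$b), cbind(g$a, side, g$b),
    cbind(0, g$a, g$b), cbind(side, g$a, g$b))
  point_cloud(unique(faces))
}

test_that("planar interiors yield essentially no keypoints", {
  s <- seq(0, 0.2, by = 0.005)
  plane <- point_cloud(as.matrix(expand.grid(x = s, y = s, z = 0)))
  keys <- iss_keypoints(plane)
  expect_lte(length(keys$indices), 0.02 * nrow(plane))
})

test_that("cube corners are all recovered as keypoints", {
  cube <- make_cube_surface()
  keys <- iss_keypoints(cube)
  expect_gt(length(keys$indices), 0)
  corners <- as.matrix(expand.grid(x = c(0, 0.1), y = c(0, 0.1),
                                   z = c(0, 0.1)))
  kp <- cloud_coords(cube)[keys$indices, , drop = FALSE]
  for (i in seq_len(nrow(corners))) {
    d <- sqrt(colSums((t(kp) - corners[i, ])^2))
    expect_lt(min(d), 2 * 0.005)
  }
})

test_that("degenerate inputs give an empty set with a warning", {
  tiny <- point_cloud(matrix(runif(9), ncol = 3))
  expect_warning(keys <- iss_keypoints(tiny), "too few")
  expect_length(keys$indices, 0)
})

test_that("keypoints are invariant under rigid motion", {
  cl <- generate_plant(plant_spec(stage = 5, seed = 9, points_per_area = 2e4))
  p <- iss_params(salient_radius = 0.02, nms_radius = 0.012)
  k1 <- iss_keypoints(cl, p)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- point_cloud(cloud_coords(cl) %*% t(R) + rep(1, nrow(cl)) %o% c(1, -2, 3))
  k2 <- iss_keypoints(rot, p)
  expect_equal(length(k1$indices), length(k2$indices), tolerance = 0.02)
  shared <- length(intersect(k1$indices, k2$indices))
  expect_gt(shared / max(length(k1$indices), 1), 0.95)
})

test_that("retention follows its definition and bounds", {
  cl <- point_cloud(cbind(c(0, 1, 0.05, 0.5), 0, 0))
  keys <- list(indices = c(1L, 2L))
  class(keys) <- "keypoint_set"
  expect_equal(keypoint_retention(cl, keys, c(3L), 0.1), 0.5)
  expect_equal(keypoint_retention(cl, keys, c(1L, 2L, 4L), 1e-9), 1.0)
  expect_equal(keypoint_retention(cl, keys, integer(0), 0.1), 0.0)
  empty <- structure(list(indices = integer(0)), class = "keypoint_set")
  expect_equal(keypoint_retention(cl, empty, 1L, 0.1), 1.0)
  expect_error(keypoint_retention(cl, keys, 1L, 0), "epsilon")

  # monotone in epsilon and in the sampled set
  cl2 <- uniform_cube_cloud(300, seed = 2)
  keys2 <- iss_keypoints(cl2)
  samp <- random_downsample(cl2, 0.2, seed = 1)
  eps <- c(0.01, 0.03, 0.1, 0.3)
  r <- vapply(eps, function(e) keypoint_retention(cl2, keys2, samp, e),
              numeric(1))
  expect_true(all(diff(r) >= 0))
  r_nested <- vapply(c(10, 60, 150, 300), function(m) {
    keypoint_retention(cl2, keys2, samp[seq_len(min(m, length(samp)))], 0.05)
  }, numeric(1))
  expect_true(all(diff(r_nested) >= 0))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("benchmark report has one row per method at matched budget", {
  cl <- generate_plant(plant_spec(stage = 6, seed = 4, points_per_area = 2e4))
  rep <- benchmark_samplers(cl, dmss_params(seed = 1), n_seeds = 1)
  expect_equal(nrow(rep), 3)
  expect_setequal(rep$method, c("rs", "fps", "dmss"))
  expect_equal(length(unique(rep$budget)), 1)
  expect_true(all(rep$retention_mean >= 0 & rep$retention_mean <= 1))
})
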