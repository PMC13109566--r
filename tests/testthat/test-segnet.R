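test_that("ball_query: fallback, hand distances, nearest-first cap", {
  pts <- cbind(c(0, 0.04, 0.2), 0, 0)
  # radius below the smallest pairwise gap: every neighbourhood is {self}
  ng <- ball_query(pts, 1:3, radius = 0.01, max_neighbors = 8)
  expect_equal(ng$sizes, rep(1L, 3))
  expect_equal(ng$neighbor, 1:3)

  ng <- ball_query(pts, 1L, radius = 0.05, max_neighbors = 8)
  expect_setequal(ng$neighbor, c(1L, 2L))
  expect_equal(ng$neighbor[1], 1L)        # self sorts first

  ng <- ball_query(pts, 1:3, radius = 1, max_neighbors = 1)
  expect_equal(ng$neighbor, 1:3)          # cap of one keeps only self
})

test_that("positional embedding: zero map at origin, translation invariance,
           identity configuration", {
  id4 <- list(W1 = diag(4), b1 = matrix(0, 1, 4), W2 = diag(4),
              b2 = matrix(0, 1, 4))
  expect_equal(positional_embedding(matrix(0, 1, 3), id4),
               matrix(0, 1, 4))
  expect_equal(positional_embedding(matrix(c(1, 2, 2), 1), id4),
               matrix(c(1, 2, 2, 3), 1))
  # psi depends only on offsets: same deltas from translated clouds
  withr::with_seed(1, {
    co <- matrix(runif(30), ncol = 3)
    pars <- list(W1 = matrix(rnorm(32), 4), b1 = matrix(rnorm(8), 1),
                 W2 = matrix(rnorm(64), 8), b2 = matrix(rnorm(8), 1))
  })
  ng1 <- ball_query(co, 1:10, 0.5, 8)
  ng2 <- ball_query(sweep(co, 2, c(5, -3, 2), `+`), 1:10, 0.5, 8)
  expect_equal(positional_embedding(ng1$delta, pars),
               positional_embedding(ng2$delta, pars))
})

test_that("geometry attention weights: hand softmax, simplex, monotone,
           uniform limit", {
  coords <- cbind(c(0, 1, 2), 0, 0)
  f <- matrix(c(0, 10, 20), ncol = 1)
  ng <- manual_neighborhood(1L, c(2L, 3L), dists = c(1, 2),
                            deltas = coords[2:3, ] - coords[rep(1, 2), ],
                            n_ref = 3)
  out <- geometry_attention(ng, f, sigma = 1)
  w <- attr(out, "weights")
  expect_equal(w, c(0.7311, 0.2689), tolerance = 1e-4)
  expect_equal(out[1, 1], 12.689, tolerance = 1e-3)

  # random neighbourhoods: rows sum to one, weights nonincreasing with d
  cl <- uniform_cube_cloud(200, seed = 3)
  ngr <- ball_query(cloud_coords(cl), 1:200, 0.2, 16)
  wr <- attr(geometry_attention(ngr, matrix(1, 200, 1), 0.05), "weights")
  sums <- tapply(wr, ngr$center_pos, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  ord <- order(ngr$center_pos, ngr$dist)
  by_center <- split(wr[ord], ngr$center_pos[ord])
  expect_true(all(vapply(by_center, function(x) all(diff(x) <= 1e-12),
                         logical(1))))

  # sigma -> infinity: uniform mean
  f2 <- matrix(rnorm(200 * 2), ncol = 2)
  out_inf <- geometry_attention(ngr, f2, sigma = 1e6)
  means <- rowsum(f2[ngr$neighbor, ], ngr$center_pos) / ngr$sizes
  expect_lt(max(abs(out_inf - means)), 1e-4)

  # single neighbour: weight one, feature passed through
  ng1 <- manual_neighborhood(1L, 2L, 0.3, matrix(c(0.3, 0, 0), 1), 3)
  expect_equal(as.numeric(geometry_attention(ng1, f, 0.5)), 10)
  expect_error(geometry_attention(ng1, f, 0), "sigma")
})

test_that("baseline self-attention: singleton identity, convexity, hand softmax", {
  Wv <- matrix(c(2), 1, 1)
  pars <- list(Wq = matrix(1), Wk = matrix(1), Wv = Wv)
  f <- matrix(c(1, 0, log(3)), ncol = 1)
  self_only <- manual_neighborhood(1L, 1L, 0, matrix(0, 1, 3), 3)
  expect_equal(as.numeric(baseline_self_attention(f, self_only, pars)),
               2 * f[1, 1])

  ng <- manual_neighborhood(1L, c(2L, 3L), c(1, 1), matrix(0, 2, 3), 3)
  # q.k logits are {0, log 3} -> weights {0.25, 0.75}
  out <- baseline_self_attention(f, ng, list(Wq = matrix(1), Wk = matrix(1),
                                             Wv = matrix(1)))
  expect_equal(as.numeric(out), 0.25 * 0 + 0.75 * log(3), tolerance = 1e-10)

  # identical neighbour features: convex weights return that feature
  f_same <- matrix(c(1, 5, 5), ncol = 1)
  out2 <- baseline_self_attention(f_same, ng, pars)
  expect_equal(as.numeric(out2), 10)
  expect_error(baseline_self_attention(matrix(1, 3, 2), ng, pars), "width")
})

test_that("multiscale aggregation concatenates one block per scale", {
  withr::with_seed(13, {
    co <- matrix(runif(60), ncol = 3)
    f <- matrix(rnorm(20 * 4), ncol = 4)
    pars <- list(
      psi = list(W1 = matrix(rnorm(4 * 6), 4), b1 = matrix(0, 1, 6),
                 W2 = matrix(rnorm(36), 6), b2 = matrix(0, 1, 6)),
      phi = lapply(1:3, function(s) list(W = matrix(rnorm(10 * 5), 10),
                                         b = matrix(0, 1, 5))))
  })
  ngs <- lapply(c(0.2, 0.4, 0.6), function(r) ball_query(co, 1:20, r, 8))
  out <- multiscale_aggregate(f, ngs, pars, sigmas = c(0.2, 0.4, 0.6))
  expect_equal(dim(out), c(20L, 15L))   # 3 scales x 5 channels

  # single point: self-only neighbourhood, zero feature difference, so the
  # output is the phi-image of [0; psi(0)] at every scale
  one <- matrix(c(0, 0, 0), 1)
  ng1 <- lapply(1:3, function(s) ball_query(one, 1L, 0.1, 4))
  f1 <- matrix(rnorm(4), 1)
  out1 <- multiscale_aggregate(f1, ng1, pars, sigmas = rep(0.1, 3))
  psi0 <- positional_embedding(matrix(0, 1, 3), pars$psi)
  msg <- pmax(cbind(matrix(0, 1, 4), psi0) %*% pars$phi[[1]]$W, 0)
  expect_equal(out1[, 1:5, drop = FALSE], msg, tolerance = 1e-12)
  expect_error(multiscale_aggregate(f, ngs[1:2], pars, sigmas = c(1, 1, 1)),
               "mismatch")
})

test_that("fuse_features equals the dense-algebra oracle", {
  withr::with_seed(4, {
    a <- matrix(rnorm(12), 4, 3)
    b <- matrix(rnorm(8), 4, 2)
    W <- matrix(rnorm(10), 5, 2)
    bias <- matrix(rnorm(2), 1, 2)
  })
  out <- fuse_features(a, b, list(W = W, b = bias))
  expect_equal(out, cbind(a, b) %*% W + rep(1, 4) %o% as.vector(bias),
               tolerance = 1e-12)
  # identity-padded map returns the concatenation
  out_id <- fuse_features(a, b, list(W = diag(5), b = matrix(0, 1, 5)))
  expect_equal(out_id, cbind(a, b))
  expect_error(fuse_features(a, b[1:2, ], list(W = W, b = bias)), "matching")
})

test_that("transition_down pools support features channel-wise", {
  withr::with_seed(5, {
    co <- matrix(runif(64 * 3), ncol = 3)
    f <- matrix(rnorm(64 * 4), ncol = 4)
  })
  pars <- list(W = diag(4), b = matrix(0, 1, 4))
  td <- transition_down(co, f, radius = 0.4, down_ratio = 0.25, pars,
                        max_neighbors = 16)
  expect_length(td$support, 16)
  expect_true(all(td$support %in% 1:64))
  expect_equal(td$coords, co[td$support, ])
  # max-pool dominates every contributing neighbour (identity + relu here)
  ng <- ball_query(co, td$support, 0.4, 16)
  tf <- pmax(f, 0)
  for (k in seq_along(td$support)) {
    nbrs <- ng$neighbor[ng$center_pos == k]
    expect_true(all(td$features[k, ] >= apply(tf[nbrs, , drop = FALSE], 2, max) - 1e-12))
  }
  # ratio one keeps every point as support
  td_all <- transition_down(co, f, 0.4, 1.0, pars, 16)
  expect_setequal(td_all$support, 1:64)
})

test_that("transition_up interpolates by inverse squared distance", {
  coarse <- cbind(c(0, 1), 0, 0)
  cf <- matrix(c(0, 10), ncol = 1)
  # fine point equidistant between the two
  mid <- transition_up(coarse, cf, matrix(c(0.5, 0, 0), 1), k_interp = 2)
  expect_equal(as.numeric(mid), 5, tolerance = 1e-6)
  # coincident fine point recovers the coarse feature
  at0 <- transition_up(coarse, cf, matrix(c(0, 0, 0), 1), k_interp = 2)
  expect_equal(as.numeric(at0), 0, tolerance = 1e-6)
  # hand-worked inverse-square weights at 0.25
  q <- transition_up(coarse, cf, matrix(c(0.25, 0, 0), 1), k_interp = 2)
  expect_equal(as.numeric(q), 10 * (16 / 9) / (16 + 16 / 9), tolerance = 1e-6)
  expect_error(transition_up(coarse[0, , drop = FALSE], cf[0, , drop = FALSE],
                             matrix(0, 1, 3)), "empty")
})

test_that("transition up then down on coincident supports round-trips", {
  withr::with_seed(6, {
    coarse <- matrix(runif(12 * 3), ncol = 3)
    cf <- matrix(rnorm(12 * 3), ncol = 3)
  })
  up <- transition_up(coarse, cf, coarse, k_interp = 3)
  expect_lt(max(abs(up - cf)), 1e-5)
})

test_that("model assembly: shapes, ablation structure and parameter counts", {
  cfg1 <- seg_config(channels = 16, n_stages = 1, max_neighbors = 8,
                     knn_k_attention = 6)
  m1 <- build_model(cfg1, seed = 2)
  cl <- uniform_cube_cloud(100, seed = 7)
  seg <- forward_segment(m1, cl)
  expect_equal(nrow(seg), 100)
  expect_true(all(c("score_leaf", "score_stem", "pred_label") %in% names(seg)))

  base <- build_model(desk_config("baseline_pt"), seed = 2)
  expect_false(any(grepl("psi|phi|fuse", names(base$params))))
  expect_true(any(grepl("att1_Wq", names(base$params))))

  n_full <- n_parameters(build_model(desk_config("full"), seed = 2))
  n_nomulti <- n_parameters(build_model(desk_config("no_multiscale"), seed = 2))
  n_nogeo <- n_parameters(build_model(desk_config("no_geometry_attention"),
                                      seed = 2))
  expect_gt(n_full, n_nomulti)
  expect_gt(n_full, n_nogeo)

  expect_error(forward_segment(build_model(seg_config(channels = c(8, 8, 8, 8),
                                                      n_stages = 4)),
                               point_cloud(matrix(runif(9), 3))),
               "fewer stages")
})

test_that("forward scores are deterministic, permutation-stable and
           translation-invariant", {
  cl <- desk_clouds(1, seed0 = 40, n_points = 180)[[1]]
  m <- build_model(desk_config(), seed = 3)
  s1 <- forward_segment(m, cl)
  s2 <- forward_segment(m, cl)
  expect_identical(s1$score_leaf, s2$score_leaf)

  shifted <- dplyr::mutate(cl, x = x + 4, y = y - 2, z = z + 0.5)
  s3 <- forward_segment(m, shifted)
  expect_lt(max(abs(s1$score_leaf - s3$score_leaf)), 1e-5)

  perm <- withr::with_seed(8, sample(nrow(cl)))
  s4 <- forward_segment(m, cl[perm, ])
  expect_lt(max(abs(s1$score_leaf[perm] - s4$score_leaf)), 1e-5)
})

test_that("height-normalized radii give scale-invariant neighbour sets", {
  cl <- desk_clouds(1, seed0 = 50, n_points = 150)[[1]]
  cfg <- desk_config()
  p1 <- stemleaf:::build_pyramid(cloud_coords(cl), cfg)
  p2 <- stemleaf:::build_pyramid(cloud_coords(cl) * 2, cfg)
  for (l in seq_along(p1$levels)) {
    for (s in seq_along(p1$levels[[l]]$balls)) {
      expect_identical(p1$levels[[l]]$balls[[s]]$neighbor,
                       p2$levels[[l]]$balls[[s]]$neighbor)
    }
  }
})

test_that("checkpoints round-trip through save_model/load_model", {
  m <- build_model(desk_config(), seed = 4)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, f)
  m2 <- load_model(f)
  expect_equal(m2$params, m$params)
  expect_equal(m2$config$ablation, "full")
  g <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(unrelated = 1), g)
  expect_error(load_model(g), "checkpoint")
})
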