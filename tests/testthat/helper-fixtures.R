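# Shared fixtures and independent oracles, all built in code.

# regular lattice cloud, one point per site
lattice_cloud <- function(n_side = 4, spacing = 0.1) {
  g <- expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                   z = seq_len(n_side))
  point_cloud(as.matrix(g) * spacing)
}

uniform_cube_cloud <- function(n = 2000, side = 0.5, seed = 1) {
  withr::with_seed(seed, point_cloud(matrix(runif(3 * n, 0, side), ncol = 3)))
}

# identical per-voxel occupancy to the uniform cube, but in a fraction of
# interior cells the points collapse towards the cell centre, so only the
# sub-voxel (local density) CV rises -- a two-density cube at fine scale
clumped_cube_cloud <- function(n = 2000, side = 0.5, seed = 1,
                               cell = 0.05, frac = 0.3, shrink = 0.08) {
  withr::with_seed(seed, {
    xyz <- matrix(runif(3 * n, 0, side), ncol = 3)
    idx <- floor(xyz / cell)
    n_cells <- side / cell
    interior <- rowSums(idx >= 1 & idx <= n_cells - 2) == 3
    key <- paste(idx[, 1], idx[, 2], idx[, 3])
    cells <- unique(key[interior])
    chosen <- sample(cells, round(frac * length(cells)))
    hit <- key %in% chosen
    ctr <- (idx + 0.5) * cell
    xyz[hit, ] <- ctr[hit, ] + shrink * (xyz[hit, ] - ctr[hit, ])
    point_cloud(xyz)
  })
}

# brute-force farthest-point sampling oracle: argmax of min distance,
# ties to the lowest index
fps_oracle <- function(coords, m, start) {
  n <- nrow(coords)
  sel <- integer(m)
  sel[1] <- start
  mind <- rep(Inf, n)
  for (s in seq_len(m - 1)) {
    p <- coords[sel[s], ]
    d <- sqrt(rowSums(sweep(coords, 2, p)^2))
    mind <- pmin(mind, d)
    mind[sel[seq_len(s)]] <- -Inf
    sel[s + 1] <- which.max(mind)   # which.max takes the lowest tied index
  }
  sel
}

# population coefficient of variation
cv_oracle <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2)) / mu
}

# brute-force all-pairs kNN density (rho_i = k / sum of squared distances)
knn_density_oracle <- function(coords, k) {
  n <- nrow(coords)
  vapply(seq_len(n), function(i) {
    d2 <- colSums((t(coords) - coords[i, ])^2)
    d2 <- sort(d2[-i])[seq_len(k)]
    k / sum(d2)
  }, numeric(1))
}

# hand-buildable neighbourhood (single center, explicit pair distances)
manual_neighborhood <- function(center, neighbors, dists, deltas, n_ref) {
  structure(list(center = rep(center, length(neighbors)),
                 neighbor = neighbors,
                 center_pos = rep(1L, length(neighbors)),
                 dist = dists, delta = deltas,
                 sizes = length(neighbors), centers = center, n_ref = n_ref),
            class = "neighborhood_index")
}

# small labelled training clouds: early-stage plants thinned by FPS so the
# desk-scale network trains in seconds
desk_clouds <- function(n, seed0, stage = 2, n_points = 220) {
  lapply(seq_len(n), function(i) {
    cl <- generate_plant(plant_spec(stage = stage, seed = seed0 + i))
    idx <- farthest_point_sample(cloud_coords(cl), n_points, seed = seed0 + i)
    cl[idx, ]
  })
}

desk_config <- function(ablation = "full") {
  seg_config(channels = c(16, 32), n_stages = 2, max_neighbors = 12,
             knn_k_attention = 8, ablation = ablation)
}
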