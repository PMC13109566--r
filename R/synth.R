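#' Specify a synthetic plant
#'
#' Describes a procedurally generated, labelled crop-like point cloud.
#' Growth stage drives plant height (linearly from 0.15 m at stage 1 to
#' 1.20 m at stage 12 for the soybean analogue), leaf count, canopy point
#' density and occlusion, so late-stage clouds are taller, denser, more
#' overlapped and more non-uniform than early ones -- the statistical
#' structure the adaptive sampler and the segmentation network assume.
#'
#' @param crop One of `"soybean_like"`, `"maize_like"`, `"tomato_like"`.
#' @param stage Ordinal growth stage, 1..12 for soybean-like plants or a day
#'   index (1..20) for the maize/tomato analogues.
#' @param height Plant height in metres; defaults to the stage-driven map.
#' @param n_leaves Leaf (leaflet) count; defaults to a stage-driven count.
#' @param n_branches Branch count; defaults stage-driven.
#' @param points_per_area Surface point density, points per square metre.
#' @param noise_sd Gaussian coordinate noise, metres.
#' @param occlusion_factor Fraction of view-hidden points removed, `[0, 1)`;
#'   defaults stage-driven (late stages are more occluded).
#' @param cultivar_id Integer; cultivars differ by systematic height and
#'   leaf-size offsets.
#' @param seed Integer seed; generation is fully deterministic per spec+seed.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(crop = c("soybean_like", "maize_like", "tomato_like"),
                       stage = 6, height = NULL, n_leaves = NULL,
                       n_branches = NULL, points_per_area = 8e4,
                       noise_sd = 0.0015, occlusion_factor = NULL,
                       cultivar_id = 1L, seed = 1L) {
  crop <- match.arg(crop)
  max_stage <- if (crop == "soybean_like") 12 else 20
  if (!is.numeric(stage) || length(stage) != 1 || stage < 1 || stage > max_stage) {
    stop("`stage` must be in [1, ", max_stage, "] for crop ", crop, call. = FALSE)
  }
  sf <- (stage - 1) / (max_stage - 1)   # stage fraction in [0, 1]
  cult_h <- 1 + 0.06 * (cultivar_id - 3)   # systematic cultivar offsets
  cult_l <- 1 + 0.04 * (cultivar_id - 3)
  if (is.null(height)) {
    height <- cult_h * switch(crop,
      soybean_like = 0.15 + sf * (1.20 - 0.15),
      maize_like = 0.12 + sf * 0.45,
      tomato_like = 0.10 + sf * 0.35)
  }
  if (height < 0.10 || height > 1.30) {
    stop("`height` must be within [0.10, 1.30] m", call. = FALSE)
  }
  if (is.null(n_leaves)) {
    n_leaves <- switch(crop,
      soybean_like = 2L + 3L * as.integer(stage),       # unifoliates + trifoliates
      maize_like = 2L + as.integer(ceiling(stage / 2)),
      tomato_like = 3L + as.integer(ceiling(stage / 2)))
  }
  if (n_leaves < 1) stop("`n_leaves` must be >= 1", call. = FALSE)
  if (is.null(n_branches)) {
    n_branches <- if (crop == "soybean_like") max(0L, as.integer(stage) - 5L) else 0L
  }
  if (is.null(occlusion_factor)) occlusion_factor <- 0.05 + 0.25 * sf
  if (occlusion_factor < 0 || occlusion_factor >= 1) {
    stop("`occlusion_factor` must lie in [0, 1)", call. = FALSE)
  }
  if (points_per_area <= 0) stop("`points_per_area` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be nonnegative", call. = FALSE)
  structure(list(crop = crop, stage = stage, stage_frac = sf, height = height,
                 n_leaves = as.integer(n_leaves),
                 n_branches = as.integer(n_branches),
                 points_per_area = points_per_area, noise_sd = noise_sd,
                 occlusion_factor = occlusion_factor,
                 cultivar_id = as.integer(cultivar_id),
                 leaf_scale = cult_l, seed = as.integer(seed)),
            class = "plant_spec")
}

# Points on a tapering tube around a gently drifting vertical spline.
sample_stem <- function(base, height, radius, n, drift) {
  # t drawn to match the tapering surface area so density is uniform
  t <- (1 - sqrt(1 - 0.64 * runif(n))) / 0.4
  wob <- sin(2 * pi * t * 1.7)
  cx <- base[1] + drift[1] * (t^2 + 0.15 * wob)
  cy <- base[2] + drift[2] * (t^2 + 0.15 * wob)
  cz <- base[3] + height * t
  phi <- runif(n, 0, 2 * pi)
  r <- radius * (1 - 0.4 * t)       # taper towards the tip
  cbind(cx + r * cos(phi), cy + r * sin(phi), cz)
}

# Points on a drooping elliptical leaf patch in a local frame defined by
# azimuth (about vertical) and pitch (tilt from horizontal). clump_frac of
# the points are drawn from tight micro-clusters on the patch instead of
# uniformly: the sub-voxel densification that overlapping foliage produces
# in multi-view reconstructions.
sample_leaf <- function(attach, a, b, azimuth, pitch, droop, n,
                        clump_frac = 0) {
  r <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  u <- r * cos(th)                  # along the major axis, [-1, 1]
  v <- r * sin(th)
  n_cl <- as.integer(round(clump_frac * n))
  if (n_cl > 0) {
    k <- sample(4:7, 1)
    cu <- runif(k, -0.6, 0.6); cv <- runif(k, -0.6, 0.6)
    pick <- sample(k, n_cl, replace = TRUE)
    sdl <- 0.05                     # cluster spread, fraction of the semi-axis
    ii <- seq_len(n_cl)             # clumped points replace the first n_cl draws
    u[ii] <- pmin(1, pmax(-1, cu[pick] + stats::rnorm(n_cl, 0, sdl)))
    v[ii] <- pmin(1, pmax(-1, cv[pick] + stats::rnorm(n_cl, 0, sdl)))
  }
  # local coordinates: major axis points away from the stem,
  # petiole end (u = -1) maps to the attachment point
  lx <- a * (u + 1)
  ly <- b * v
  lz <- -droop * a * (u + 1)^2 / 2 - droop * a * v^2 / 2
  cp <- cos(pitch); sp <- sin(pitch)
  px <- cp * lx - sp * lz
  pz <- sp * lx + cp * lz
  ca <- cos(azimuth); sa <- sin(azimuth)
  cbind(attach[1] + ca * px - sa * ly,
        attach[2] + sa * px + ca * ly,
        attach[3] + pz)
}

# Approximate hidden-point removal: spherical angular bins around a random
# viewpoint; points substantially behind the nearest point of their bin are
# candidates for removal.
occlude <- function(xyz, frac, height, bin_deg = 1.5) {
  if (frac <= 0 || nrow(xyz) < 10) return(rep(TRUE, nrow(xyz)))
  ctr <- colMeans(xyz)
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  vp <- ctr + dir * 2.5 * height
  d <- sweep(xyz, 2, vp)
  r <- sqrt(rowSums(d^2))
  theta <- atan2(d[, 2], d[, 1])
  phi <- acos(pmin(1, pmax(-1, d[, 3] / r)))
  res <- bin_deg * pi / 180
  key <- paste(floor(theta / res), floor(phi / res))
  rmin <- stats::ave(r, key, FUN = min)
  hidden <- which(r > rmin + 0.02 * height)
  drop <- hidden[runif(length(hidden)) < frac]
  keep <- rep(TRUE, nrow(xyz))
  keep[drop] <- FALSE
  keep
}

#' Generate a labelled synthetic plant point cloud
#'
#' Builds a stem (label 1) as points on tapering tubes around noisy splines
#' (main stem plus stage-dependent branches) and leaves (label 0) as points
#' on drooping elliptical patches attached along the stem -- trifoliate
#' groups for the soybean analogue, long narrow blades for maize, compact
#' compound clusters for tomato. Point budgets are allocated so the canopy
#' is several times denser than the stem at late stages, occlusion removes a
#' fraction of view-hidden points, and Gaussian noise perturbs coordinates.
#'
#' @param spec A [plant_spec()].
#' @return A labelled [point_cloud()] tibble.
#' @export
generate_plant <- function(spec) {
  if (!inherits(spec, "plant_spec")) spec <- do.call(plant_spec, spec)
  with_seed(spec$seed, generate_plant_impl(spec))
}

generate_plant_impl <- function(spec) {
  h <- spec$height
  sf <- spec$stage_frac
  # surface areas drive the point budget
  stem_r <- 0.004 + 0.004 * sf
  leaf_a <- spec$leaf_scale * switch(spec$crop,
    soybean_like = 0.020 + 0.040 * sf,
    maize_like = 0.060 + 0.140 * sf,
    tomato_like = 0.018 + 0.030 * sf)
  leaf_b <- leaf_a * switch(spec$crop, soybean_like = 0.6,
                            maize_like = 0.12, tomato_like = 0.55)
  stem_area <- 2 * pi * stem_r * h * (1 + 0.35 * spec$n_branches)
  leaf_area <- pi * leaf_a * leaf_b * spec$n_leaves
  n_total <- max(600L, as.integer(round(spec$points_per_area *
                                          (stem_area + leaf_area))))
  # canopy densification with stage: upper-canopy leaves carry a density
  # boost, emulating overlapping-surface reconstruction artefacts
  p_stem <- 0.36 - 0.16 * sf
  n_stem_total <- max(60L, as.integer(round(p_stem * n_total)))
  n_leaf_total <- n_total - n_stem_total

  base <- c(0, 0, 0)
  drift <- stats::rnorm(2, 0, 0.04 * h)
  n_branch <- spec$n_branches
  n_main <- as.integer(round(n_stem_total / (1 + 0.5 * n_branch)))
  stem_pts <- sample_stem(base, h, stem_r, n_main, c(drift, 0))
  branch_attach <- list()
  if (n_branch > 0) {
    n_each <- max(20L, as.integer(round((n_stem_total - n_main) / n_branch)))
    for (b in seq_len(n_branch)) {
      t0 <- 0.15 + 0.5 * (b - 1) / max(1, n_branch)
      a0 <- c(base[1] + drift[1] * t0^2, base[2] + drift[2] * t0^2, h * t0)
      ang <- runif(1, 0, 2 * pi)
      bdrift <- c(cos(ang), sin(ang)) * 0.25 * h
      bp <- sample_stem(a0, 0.35 * h, 0.6 * stem_r, n_each, c(bdrift, 0))
      stem_pts <- rbind(stem_pts, bp)
      branch_attach[[b]] <- list(base = a0, drift = bdrift, len = 0.35 * h)
    }
  }

  # leaf attachments: spiral phyllotaxy along the main stem (and branches)
  nl <- spec$n_leaves
  leaf_rows <- vector("list", nl)
  golden <- 137.5 * pi / 180
  # per-leaf density weight: upper leaves denser at late stages
  tpos <- 0.18 + 0.78 * (seq_len(nl) - 0.5) / nl
  size_jit <- runif(nl, 0.8, 1.15)
  # counts proportional to true leaf area (uniform scan density), with an
  # upper-canopy densification that grows with stage
  boost <- (1 + 0.8 * sf * (tpos > 0.5)) * size_jit^2
  wts <- boost / sum(boost)
  n_leaf <- pmax(25L, as.integer(round(wts * n_leaf_total)))
  for (i in seq_len(nl)) {
    t0 <- tpos[i]
    att <- c(base[1] + drift[1] * t0^2, base[2] + drift[2] * t0^2, h * t0)
    az <- (i - 1) * golden + runif(1, -0.2, 0.2)
    pitch <- switch(spec$crop,
      soybean_like = runif(1, -0.5, 0.1),
      maize_like = runif(1, 0.4, 0.9),
      tomato_like = runif(1, -0.4, 0.2))
    droop <- switch(spec$crop, soybean_like = 0.35, maize_like = 0.9,
                    tomato_like = 0.45)
    # petiole offset moves soybean leaflets away from the stem axis
    pet <- if (spec$crop == "soybean_like") 0.25 * leaf_a else 0.05 * leaf_a
    att <- att + c(cos(az), sin(az), 0) * pet
    clump <- if (tpos[i] > 0.45) 0.7 * sf else 0.1 * sf
    leaf_rows[[i]] <- sample_leaf(att, leaf_a * size_jit[i], leaf_b * size_jit[i],
                                  az, pitch, droop, n_leaf[i],
                                  clump_frac = clump)
  }
  leaf_pts <- do.call(rbind, leaf_rows)

  xyz <- rbind(stem_pts, leaf_pts)
  lab <- c(rep(1L, nrow(stem_pts)), rep(0L, nrow(leaf_pts)))
  keep <- occlude(xyz, spec$occlusion_factor, h)
  # never drop a whole class
  for (cl in c(0L, 1L)) {
    if (!any(keep & lab == cl)) keep[which(lab == cl)[1]] <- TRUE
  }
  xyz <- xyz[keep, , drop = FALSE]
  lab <- lab[keep]
  if (spec$noise_sd > 0) {
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$noise_sd), ncol = 3)
  }
  point_cloud(xyz, label = lab,
              name = sprintf("%s_c%d_s%02d_seed%d", spec$crop,
                             spec$cultivar_id, round(spec$stage), spec$seed))
}

#' Generate a synthetic multi-cultivar dataset
#'
#' Writes one cloud per cultivar x stage x replicate cell (cultivars differ
#' by systematic height and leaf-size offsets) and returns a manifest tibble
#' recording the file, crop, cultivar, stage, plant id and seed of each.
#'
#' @param crop Crop analogue, as in [plant_spec()].
#' @param n_cultivars Number of cultivars (>= 1).
#' @param stages Integer vector of stages to generate.
#' @param plants_per_cell Replicates per cultivar x stage cell.
#' @param seed Integer seed; per-cloud seeds are derived deterministically.
#' @param dir Output directory (created if missing); `NULL` keeps clouds in
#'   memory in a `cloud` list-column instead of writing files.
#' @param format On-disk format for [write_point_cloud()].
#' @param ... Extra arguments passed to [plant_spec()] (e.g.
#'   `points_per_area`).
#' @return A manifest tibble: `path` (or `cloud`), `crop`, `cultivar`,
#'   `stage`, `plant`, `seed`, `n_points`.
#' @export
generate_dataset <- function(crop = "soybean_like", n_cultivars = 5,
                             stages = 1:12, plants_per_cell = 1,
                             seed = 1L, dir = NULL, format = "ply", ...) {
  stopifnot(n_cultivars >= 1, plants_per_cell >= 1)
  grid <- tidyr::expand_grid(cultivar = seq_len(n_cultivars),
                             stage = stages, plant = seq_len(plants_per_cell))
  grid$seed <- seed + seq_len(nrow(grid)) * 101L
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::pmap(grid, function(cultivar, stage, plant, seed) {
    cloud <- generate_plant(plant_spec(crop = crop, stage = stage,
                                       cultivar_id = cultivar, seed = seed, ...))
    out <- tibble::tibble(crop = crop, cultivar = cultivar, stage = stage,
                          plant = plant, seed = seed, n_points = nrow(cloud))
    if (is.null(dir)) {
      out$cloud <- list(cloud)
    } else {
      path <- file.path(dir, paste0(attr(cloud, "name"), "_p", plant, ".", format))
      write_point_cloud(cloud, path, format = format)
      out$path <- path
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' Vertical density profile of a cloud
#'
#' Splits the cloud into horizontal slabs along the vertical axis and
#' summarises k-nearest-neighbour local densities per slab; a diagnostic for
#' the stage-dependent density non-uniformity the generator must produce.
#'
#' @param cloud A point-cloud data frame.
#' @param n_bins Number of vertical bins (>= 2).
#' @param k Neighbour count for the local density estimate.
#' @return A tibble with one row per bin: `bin`, `z_lo`, `z_hi`, `n`,
#'   `rho_q25`, `rho_median`, `rho_q75`.
#' @export
density_profile <- function(cloud, n_bins = 6, k = 16) {
  validate_point_cloud(cloud)
  stopifnot(n_bins >= 2)
  ds <- knn_density_stats(cloud, k = k, cv_v = 0)
  z <- cloud$z
  brks <- seq(min(z), max(z), length.out = n_bins + 1)
  bin <- pmin(n_bins, pmax(1L, findInterval(z, brks, rightmost.closed = TRUE)))
  tibble::tibble(bin = bin, rho = ds$rho, z = z) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(z_lo = min(z), z_hi = max(z), n = dplyr::n(),
                     rho_q25 = stats::quantile(rho, 0.25),
                     rho_median = stats::median(rho),
                     rho_q75 = stats::quantile(rho, 0.75),
                     .groups = "drop") |>
    dplyr::arrange(bin)
}
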