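#' Parameters of the intrinsic-shape-signature keypoint detector
#'
#' When radii are not given they default to multiples of the cloud's mean
#' nearest-neighbour spacing (6x for the saliency radius, 4x for
#' non-maximum suppression), the customary ISS setting.
#'
#' @param salient_radius Neighbourhood radius for the covariance test, metres.
#' @param nms_radius Non-maximum-suppression radius, metres.
#' @param gamma_21,gamma_32 Eigenvalue-ratio thresholds in (0, 1).
#' @param min_neighbors Minimum neighbour count for a candidate (>= 3).
#' @return A list of class `iss_params`.
#' @export
iss_params <- function(salient_radius = NULL, nms_radius = NULL,
                       gamma_21 = 0.975, gamma_32 = 0.975,
                       min_neighbors = 5) {
  stopifnot(gamma_21 > 0, gamma_21 < 1, gamma_32 > 0, gamma_32 < 1,
            min_neighbors >= 3)
  structure(list(salient_radius = salient_radius, nms_radius = nms_radius,
                 gamma_21 = gamma_21, gamma_32 = gamma_32,
                 min_neighbors = as.integer(min_neighbors)),
            class = "iss_params")
}

#' Mean nearest-neighbour spacing of a cloud
#'
#' @param cloud A point-cloud data frame with at least two points.
#' @return Mean distance to the first nearest neighbour, metres.
#' @export
mean_nn_spacing <- function(cloud) {
  validate_point_cloud(cloud)
  if (nrow(cloud) < 2) stop("need at least two points", call. = FALSE)
  mean(sqrt(cpp_knn(cloud_coords(cloud), 1L)$d2[, 1]))
}

resolve_iss <- function(cloud, params) {
  if (is.null(params$salient_radius) || is.null(params$nms_radius)) {
    sp <- mean_nn_spacing(cloud)
    if (is.null(params$salient_radius)) params$salient_radius <- 6 * sp
    if (is.null(params$nms_radius)) params$nms_radius <- 4 * sp
  }
  stopifnot(params$salient_radius > 0, params$nms_radius > 0)
  params
}

#' Intrinsic-shape-signature keypoints
#'
#' For each point, the eigenvalues `l1 >= l2 >= l3` of the (unweighted)
#' covariance of its salient-radius neighbourhood are computed; candidates
#' must satisfy `l2/l1 < gamma_21` and `l3/l2 < gamma_32` and have at least
#' `min_neighbors` neighbours. Non-maximum suppression keeps a candidate
#' only if its `l3` (the saliency) is maximal within `nms_radius`, ties
#' going to the lowest index. Deterministic.
#'
#' @param cloud A point-cloud data frame.
#' @param params An [iss_params()] object.
#' @return A list of class `keypoint_set`: `indices` (1-based rows of
#'   `cloud`), `saliency` (their `l3` values) and the resolved `params`.
#'   Too few points yields an empty set with a warning.
#' @export
iss_keypoints <- function(cloud, params = iss_params()) {
  validate_point_cloud(cloud)
  n <- nrow(cloud)
  if (n < params$min_neighbors + 1) {
    warning("cloud has too few points for keypoint detection; returning empty set")
    return(structure(list(indices = integer(0), saliency = numeric(0),
                          params = params), class = "keypoint_set"))
  }
  params <- resolve_iss(cloud, params)
  xyz <- cloud_coords(cloud)
  ce <- cpp_local_cov_eigs(xyz, params$salient_radius)
  ev <- ce$eigs
  ok <- ce$n_neighbors >= params$min_neighbors &
    ev[, 1] > 0 & ev[, 2] > 0 &
    ev[, 2] / ev[, 1] < params$gamma_21 &
    ev[, 3] / ev[, 2] < params$gamma_32
  cand <- which(ok)
  if (!length(cand)) {
    return(structure(list(indices = integer(0), saliency = numeric(0),
                          params = params), class = "keypoint_set"))
  }
  sal <- ev[, 3]
  neigh <- cpp_ball_query(xyz, cand, params$nms_radius, n)
  keep <- vapply(seq_along(cand), function(t) {
    i <- cand[t]
    nb <- neigh$idx[[t]]
    rivals <- nb[nb != i & nb %in% cand]
    if (!length(rivals)) return(TRUE)
    best <- max(sal[rivals])
    sal[i] > best || (sal[i] == best && i < min(rivals[sal[rivals] == best]))
  }, logical(1))
  structure(list(indices = cand[keep], saliency = sal[cand[keep]],
                 params = params), class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat("ISS keypoint set:", length(x$indices), "keypoints",
      sprintf("(salient radius %.4g m, nms %.4g m)\n",
              x$params$salient_radius %||% NA, x$params$nms_radius %||% NA))
  invisible(x)
}

#' Keypoint retention of a sampled subset
#'
#' A keypoint counts as retained when some sampled point lies within
#' `epsilon` of it; the retention ratio is `retained / |keypoints|`
#' (1 when there are no keypoints).
#'
#' @param cloud The source point-cloud data frame.
#' @param keys A [iss_keypoints()] result (or an integer index vector).
#' @param sampled Integer vector of sampled row indices.
#' @param epsilon Distance tolerance in metres (> 0).
#' @return A fraction in `[0, 1]`.
#' @export
keypoint_retention <- function(cloud, keys, sampled, epsilon) {
  validate_point_cloud(cloud)
  if (!is.numeric(epsilon) || epsilon <= 0) {
    stop("`epsilon` must be positive", call. = FALSE)
  }
  idx <- if (inherits(keys, "keypoint_set")) keys$indices else as.integer(keys)
  if (!length(idx)) return(1.0)
  if (!length(sampled)) return(0.0)
  xyz <- cloud_coords(cloud)
  d <- cpp_min_cross_dist(xyz[idx, , drop = FALSE],
                          xyz[sampled, , drop = FALSE])
  mean(d <= epsilon)
}

#' Benchmark samplers by keypoint retention
#'
#' Runs random sampling, plain farthest-point sampling, and the dynamic
#' multi-stage sampler at a *matched* budget (the point count the dynamic
#' sampler realises) over `n_seeds` seeds, and reports mean and standard
#' deviation of ISS-keypoint retention plus wall-clock time per method.
#' Timing is informational only.
#'
#' @param cloud A labelled or unlabelled point-cloud data frame.
#' @param params A [dmss_params()] object.
#' @param iss An [iss_params()] object.
#' @param epsilon Retention tolerance in metres, or `NULL` for the default
#'   2x mean nearest-neighbour spacing of `cloud`.
#' @param n_seeds Number of seeds (>= 1).
#' @return A tibble with one row per method: `method`, `budget`,
#'   `retention_mean`, `retention_sd`, `seconds`.
#' @export
benchmark_samplers <- function(cloud, params = dmss_params(),
                               iss = iss_params(), epsilon = NULL,
                               n_seeds = 20) {
  validate_point_cloud(cloud)
  stopifnot(n_seeds >= 1)
  if (is.null(epsilon)) epsilon <- 2 * mean_nn_spacing(cloud)
  keys <- iss_keypoints(cloud, iss)
  n <- nrow(cloud)
  ret <- list(rs = numeric(n_seeds), fps = numeric(n_seeds),
              dmss = numeric(n_seeds))
  secs <- c(rs = 0, fps = 0, dmss = 0)
  budgets <- integer(n_seeds)
  for (s in seq_len(n_seeds)) {
    p <- params
    p$seed <- params$seed + s - 1L
    t0 <- proc.time()[["elapsed"]]
    dres <- dmss_sample(cloud, p)
    secs[["dmss"]] <- secs[["dmss"]] + proc.time()[["elapsed"]] - t0
    budget <- length(dres$final_indices)
    budgets[s] <- budget
    ret$dmss[s] <- keypoint_retention(cloud, keys, dres$final_indices, epsilon)

    t0 <- proc.time()[["elapsed"]]
    rs_idx <- random_downsample(cloud, budget / n, seed = p$seed)
    secs[["rs"]] <- secs[["rs"]] + proc.time()[["elapsed"]] - t0
    ret$rs[s] <- keypoint_retention(cloud, keys, rs_idx, epsilon)

    t0 <- proc.time()[["elapsed"]]
    fps_idx <- farthest_point_sample(cloud_coords(cloud), budget, seed = p$seed)
    secs[["fps"]] <- secs[["fps"]] + proc.time()[["elapsed"]] - t0
    ret$fps[s] <- keypoint_retention(cloud, keys, fps_idx, epsilon)
  }
  tibble::tibble(
    method = c("rs", "fps", "dmss"),
    budget = round(mean(budgets)),
    retention_mean = c(mean(ret$rs), mean(ret$fps), mean(ret$dmss)),
    retention_sd = c(stats::sd(ret$rs), stats::sd(ret$fps), stats::sd(ret$dmss)),
    seconds = as.numeric(secs[c("rs", "fps", "dmss")]),
    n_seeds = n_seeds,
    n_keypoints = length(keys$indices),
    epsilon = epsilon
  )
}
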