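#' Parameters of the dynamic multi-stage sampler
#'
#' The sampler thins a cloud in two stages: a coarse uniform random stage
#' retaining `stage1_ratio` of the points, then farthest-point sampling on
#' that subset at a rate adapted to the cloud's structural complexity. The
#' adaptive rate is `r_base * (w_v + lambda * w_d)` where `w_v = 1/(1 + CV_v)`
#' derives from the coefficient of variation of per-voxel occupancy and
#' `w_d = CV_d / (CV_v + CV_d)` from the CV of k-nearest-neighbour local
#' densities. The overall retained fraction (relative to the original cloud)
#' is clamped to `[clamp_lo, clamp_hi]`.
#'
#' @param voxel_edge Voxel edge length in metres (default 0.05).
#' @param knn_k Neighbour count for local density (default 50).
#' @param r_base Base FPS fraction applied to the stage-1 set (default 0.5).
#' @param lambda_weight Weight of the density term in the rate rule and in
#'   the joint complexity diagnostic (default 0.5).
#' @param stage1_ratio Fraction retained by the random stage (default 0.10).
#' @param clamp_lo,clamp_hi Bounds on the overall retained fraction
#'   (defaults 0.02 and 0.08).
#' @param density_reciprocal Use the reciprocal density reading
#'   `sum(d^2)/k` instead of `k/sum(d^2)` (the CVs of the two readings
#'   agree to first order and closely in practice).
#' @param seed Integer seed for the random stage.
#' @return A list of class `dmss_params`.
#' @export
dmss_params <- function(voxel_edge = 0.05, knn_k = 50, r_base = 0.5,
                        lambda_weight = 0.5, stage1_ratio = 0.10,
                        clamp_lo = 0.02, clamp_hi = 0.08,
                        density_reciprocal = FALSE, seed = 1L) {
  stopifnot(voxel_edge > 0, knn_k >= 1, r_base > 0, r_base <= 1,
            lambda_weight >= 0, stage1_ratio > 0, stage1_ratio <= 1,
            clamp_lo > 0, clamp_lo < clamp_hi, clamp_hi <= 1)
  structure(list(voxel_edge = voxel_edge, knn_k = as.integer(knn_k),
                 r_base = r_base, lambda_weight = lambda_weight,
                 stage1_ratio = stage1_ratio, clamp_lo = clamp_lo,
                 clamp_hi = clamp_hi, density_reciprocal = density_reciprocal,
                 seed = as.integer(seed)),
            class = "dmss_params")
}

#' Uniform random down-sampling
#'
#' Retains `max(1, round(ratio * N))` distinct points chosen uniformly
#' without replacement; deterministic for a fixed seed.
#'
#' @param cloud A point-cloud data frame.
#' @param ratio Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Integer vector of retained row indices (sorted).
#' @export
random_downsample <- function(cloud, ratio, seed = 1L) {
  validate_point_cloud(cloud)
  n <- nrow(cloud)
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0 || ratio > 1) {
    stop("`ratio` must be a single value in (0, 1]", call. = FALSE)
  }
  m <- max(1L, as.integer(round(ratio * n)))
  if (m >= n) return(seq_len(n))
  sort(with_seed(seed, sample.int(n, m)))
}

#' Farthest-point sampling
#'
#' Iteratively selects the point maximising the minimum Euclidean distance
#' to the already-selected set; the first point is drawn uniformly from the
#' seed and ties go to the lowest index.
#'
#' @param coords An M x 3 numeric matrix (or a point-cloud data frame).
#' @param m Number of points to select, `1 <= m <= M`.
#' @param seed Integer seed choosing the start point.
#' @param start Optional explicit 1-based start index overriding the seed.
#' @return Integer vector of `m` distinct indices in selection order.
#' @export
farthest_point_sample <- function(coords, m, seed = 1L, start = NULL) {
  if (is.data.frame(coords)) coords <- cloud_coords(coords)
  n <- nrow(coords)
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m > n) {
    stop("`m` must be an integer in [1, ", n, "]", call. = FALSE)
  }
  if (is.null(start)) start <- with_seed(seed, sample.int(n, 1))
  cpp_fps(coords, as.integer(m), as.integer(start))
}

#' Voxel-occupancy statistics
#'
#' Voxelises the cloud on a grid anchored at the bounding-box minimum corner
#' (half-open cells of the given edge) and summarises the occupied voxels:
#' mean and population standard deviation of per-voxel point counts, their
#' coefficient of variation `CV_v`, and the sparsity weight
#' `w_v = 1 / (1 + CV_v)`.
#'
#' @param cloud A point-cloud data frame.
#' @param voxel_edge Voxel edge length in metres.
#' @return A one-row tibble: `occupied_count`, `mean_occupancy`,
#'   `sd_occupancy`, `cv_v`, `w_v`.
#' @export
voxel_occupancy_stats <- function(cloud, voxel_edge = 0.05) {
  validate_point_cloud(cloud)
  stopifnot(voxel_edge > 0)
  xyz <- cloud_coords(cloud)
  lo <- apply(xyz, 2, min)
  cell <- floor(sweep(xyz, 2, lo) / voxel_edge)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  counts <- as.integer(table(key))
  mu <- mean(counts)
  sigma <- sqrt(mean((counts - mu)^2))   # population sd over occupied voxels
  cv <- if (mu > 0) sigma / mu else 0
  tibble::tibble(occupied_count = length(counts), mean_occupancy = mu,
                 sd_occupancy = sigma, cv_v = cv, w_v = 1 / (1 + cv))
}

#' k-nearest-neighbour density statistics
#'
#' For each point the local density is `rho_i = k / sum_j ||p_i - p_j||^2`
#' over its `k` nearest neighbours (self excluded; `k` truncated to `N - 1`).
#' Returns the density vector with its mean, population standard deviation,
#' coefficient of variation `CV_d`, and the complexity weight
#' `w_d = CV_d / (CV_v + CV_d)` for the supplied paired `cv_v`.
#'
#' @param cloud A point-cloud data frame with at least two points.
#' @param k Neighbour count (default 50).
#' @param cv_v The voxel-occupancy CV the weight is paired with.
#' @param reciprocal Use the reciprocal reading `sum(d^2)/k` instead.
#' @return A list: `rho` (length-N vector), `mean_rho`, `sd_rho`, `cv_d`, `w_d`.
#' @export
knn_density_stats <- function(cloud, k = 50, cv_v = 0, reciprocal = FALSE) {
  validate_point_cloud(cloud)
  n <- nrow(cloud)
  if (n < 2) stop("density statistics require at least two points", call. = FALSE)
  k_eff <- min(as.integer(k), n - 1L)
  res <- cpp_knn(cloud_coords(cloud), k_eff)
  ssq <- rowSums(res$d2)
  rho <- if (reciprocal) ssq / k_eff else k_eff / ssq
  mu <- mean(rho)
  sigma <- sqrt(mean((rho - mu)^2))
  cv <- if (mu > 0) sigma / mu else 0
  wd <- if (cv_v + cv > 0) cv / (cv_v + cv) else 0
  list(rho = rho, mean_rho = mu, sd_rho = sigma, cv_d = cv, w_d = wd)
}

#' Joint structural-complexity diagnostic
#'
#' The weighted combination `lambda * cv_v + (1 - lambda) * cv_d` of the two
#' variability measures. Reported as a diagnostic alongside sampling results;
#' the sampling rate itself is driven by the weight rule of [dmss_ratio()].
#'
#' @param cv_v,cv_d Nonnegative coefficients of variation.
#' @param lambda_weight Mixing weight in `[0, 1]`.
#' @return A single number.
#' @export
joint_complexity <- function(cv_v, cv_d, lambda_weight = 0.5) {
  stopifnot(cv_v >= 0, cv_d >= 0, lambda_weight >= 0, lambda_weight <= 1)
  lambda_weight * cv_v + (1 - lambda_weight) * cv_d
}

#' Adaptive sampling rate
#'
#' Computes the raw FPS rate `r_base * (w_v + lambda * w_d)`, converts it to
#' an overall retained fraction by multiplying with `stage1_ratio`, clamps
#' that overall fraction into `[clamp_lo, clamp_hi]`, and reports the
#' post-clamp FPS rate (`overall / stage1_ratio`).
#'
#' @param w_v Sparsity weight from [voxel_occupancy_stats()].
#' @param w_d Complexity weight from [knn_density_stats()].
#' @param params A [dmss_params()] object.
#' @return A list: `r_fps`, `overall_ratio`, `raw_overall`, `clamped`.
#' @export
dmss_ratio <- function(w_v, w_d, params = dmss_params()) {
  raw_fps <- params$r_base * (w_v + params$lambda_weight * w_d)
  raw_overall <- params$stage1_ratio * raw_fps
  overall <- min(max(raw_overall, params$clamp_lo), params$clamp_hi)
  list(r_fps = overall / params$stage1_ratio, overall_ratio = overall,
       raw_overall = raw_overall, clamped = overall != raw_overall)
}

#' Dynamic multi-stage down-sampling
#'
#' Stage 1 thins the cloud uniformly at `stage1_ratio`; the complexity
#' statistics are computed on the *original* cloud; stage 2 runs
#' farthest-point sampling on the stage-1 subset at the adaptive rate of
#' [dmss_ratio()]. All indices refer to rows of the original cloud and the
#' whole procedure is reproducible from `params$seed`.
#'
#' @param cloud A point-cloud data frame large enough that stage 1 retains
#'   at least two points.
#' @param params A [dmss_params()] object.
#' @return A list of class `dmss_result`: `stage1_indices`, `final_indices`,
#'   `voxel_stats`, `density_stats`, `c_joint`, `r_fps`, `overall_ratio`
#'   (realised `|final| / N`), `target_ratio` (post-clamp rate before integer
#'   rounding), and `params`.
#' @export
dmss_sample <- function(cloud, params = dmss_params()) {
  validate_point_cloud(cloud)
  n <- nrow(cloud)
  stage1 <- random_downsample(cloud, params$stage1_ratio, seed = params$seed)
  if (length(stage1) < 2) {
    stop("stage 1 retains fewer than two points; cloud too small", call. = FALSE)
  }
  vs <- voxel_occupancy_stats(cloud, params$voxel_edge)
  ds <- knn_density_stats(cloud, k = params$knn_k, cv_v = vs$cv_v,
                          reciprocal = params$density_reciprocal)
  rr <- dmss_ratio(vs$w_v, ds$w_d, params)
  m <- max(1L, as.integer(round(rr$r_fps * length(stage1))))
  m <- min(m, length(stage1))
  sub <- cloud_coords(cloud)[stage1, , drop = FALSE]
  picked <- farthest_point_sample(sub, m, seed = params$seed + 1L)
  structure(list(stage1_indices = stage1,
                 final_indices = stage1[picked],
                 voxel_stats = vs,
                 density_stats = ds[c("mean_rho", "sd_rho", "cv_d", "w_d")],
                 c_joint = joint_complexity(vs$cv_v, ds$cv_d,
                                            params$lambda_weight),
                 r_fps = rr$r_fps,
                 overall_ratio = length(stage1[picked]) / n,
                 target_ratio = rr$overall_ratio,
                 clamped = rr$clamped,
                 n_points = n,
                 params = params),
            class = "dmss_result")
}

#' @export
print.dmss_result <- function(x, ...) {
  cat("Dynamic multi-stage sampling result\n")
  cat(sprintf("  N = %d -> stage 1: %d -> final: %d (overall %.2f%%)\n",
              x$n_points, length(x$stage1_indices), length(x$final_indices),
              100 * x$overall_ratio))
  cat(sprintf("  CV_v = %.4f (w_v = %.4f)  CV_d = %.4f (w_d = %.4f)\n",
              x$voxel_stats$cv_v, x$voxel_stats$w_v,
              x$density_stats$cv_d, x$density_stats$w_d))
  cat(sprintf("  C_joint = %.4f  r_fps = %.4f%s\n", x$c_joint, x$r_fps,
              if (x$clamped) "  [clamped]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sampling result
#'
#' @param x A `dmss_result` object.
#' @param ... Unused.
#' @return A one-row tibble of the computed statistics and realised ratios.
#' @export
tidy.dmss_result <- function(x, ...) {
  tibble::tibble(
    n_points = x$n_points,
    n_stage1 = length(x$stage1_indices),
    n_final = length(x$final_indices),
    cv_v = x$voxel_stats$cv_v, w_v = x$voxel_stats$w_v,
    cv_d = x$density_stats$cv_d, w_d = x$density_stats$w_d,
    c_joint = x$c_joint, r_fps = x$r_fps,
    target_ratio = x$target_ratio, overall_ratio = x$overall_ratio,
    clamped = x$clamped
  )
}
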