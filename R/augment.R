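#' Growth-informed point-cloud augmentations
#'
#' Three label-preserving geometric augmentations emulating field
#' acquisition variability: a rigid centre shift (equipment positioning
#' error), isotropic rescaling about the centroid (plant-size variation
#' over the 15-120 cm growth range), and a reflection through the XZ plane
#' (multi-directional viewpoints countering one-sided scanning). All are
#' deterministic per seed and never change the point count, order or
#' labels.
#'
#' @param cloud A point-cloud data frame.
#' @param shift_range Half-width of the uniform shift, metres (default 0.5).
#' @param seed Integer seed.
#' @return The transformed cloud.
#' @name augmentations
NULL

#' @rdname augmentations
#' @export
center_shift <- function(cloud, shift_range = 0.5, seed = 1L) {
  validate_point_cloud(cloud)
  if (shift_range < 0) stop("`shift_range` must be nonnegative", call. = FALSE)
  u <- with_seed(seed, runif(3, -shift_range, shift_range))
  out <- cloud
  out$x <- cloud$x + u[1]
  out$y <- cloud$y + u[2]
  out$z <- cloud$z + u[3]
  out
}

#' @rdname augmentations
#' @param lo,hi Bounds of the uniform scale factor (defaults 0.8, 1.2).
#' @export
random_scale <- function(cloud, lo = 0.8, hi = 1.2, seed = 1L) {
  validate_point_cloud(cloud)
  if (lo <= 0 || lo > hi) stop("need 0 < lo <= hi", call. = FALSE)
  s <- with_seed(seed, runif(1, lo, hi))
  ctr <- c(mean(cloud$x), mean(cloud$y), mean(cloud$z))
  out <- cloud
  out$x <- ctr[1] + s * (cloud$x - ctr[1])
  out$y <- ctr[2] + s * (cloud$y - ctr[2])
  out$z <- ctr[3] + s * (cloud$z - ctr[3])
  out
}

#' @rdname augmentations
#' @param force `NULL` for the seeded coin flip, or `TRUE`/`FALSE` to force
#'   the flip on or off.
#' @export
random_flip_xz <- function(cloud, seed = 1L, force = NULL) {
  validate_point_cloud(cloud)
  flip <- if (is.null(force)) with_seed(seed, runif(1) < 0.5) else isTRUE(force)
  if (!flip) return(cloud)
  cy <- mean(cloud$y)
  out <- cloud
  out$y <- 2 * cy - cloud$y   # reflect through the XZ plane at the centroid
  out
}

#' Augmentation configuration
#'
#' @param shift_range Centre-shift half-width, metres.
#' @param scale_lo,scale_hi Scale-factor bounds.
#' @param enable_shift,enable_scale,enable_flip Per-transform switches.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(shift_range = 0.5, scale_lo = 0.8, scale_hi = 1.2,
                           enable_shift = TRUE, enable_scale = TRUE,
                           enable_flip = TRUE) {
  stopifnot(shift_range >= 0, scale_lo > 0, scale_lo <= scale_hi)
  structure(list(shift_range = shift_range, scale_lo = scale_lo,
                 scale_hi = scale_hi, enable_shift = enable_shift,
                 enable_scale = enable_scale, enable_flip = enable_flip),
            class = "augment_config")
}

# apply the enabled augmentations with per-transform derived seeds
apply_augmentations <- function(cloud, config, seed) {
  if (is.null(config)) return(cloud)
  if (config$enable_shift) {
    cloud <- center_shift(cloud, config$shift_range, seed = seed)
  }
  if (config$enable_scale) {
    cloud <- random_scale(cloud, config$scale_lo, config$scale_hi,
                          seed = seed + 1L)
  }
  if (config$enable_flip) {
    cloud <- random_flip_xz(cloud, seed = seed + 2L)
  }
  cloud
}
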