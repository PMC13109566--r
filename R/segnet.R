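#' Configuration of the segmentation network
#'
#' Describes the geometry-aware multi-scale point-transformer used for
#' stem/leaf labelling: an encoder of per-stage blocks (multi-scale ball
#' -query aggregation with learned positional embeddings, geometry-aware
#' attention, linear fusion, farthest-point-sampling transition down)
#' mirrored by a decoder of distance-weighted transition-up and fusion
#' layers, ending in a fully connected per-point classification head.
#'
#' @param radii Three increasing ball-query radii as fractions of the plant
#'   height (defaults 0.05, 0.10, 0.15).
#' @param max_neighbors Cap on points per ball (default 32).
#' @param knn_k_attention Neighbour count of the geometry-attention
#'   neighbourhood (default 16).
#' @param channels Per-stage feature widths (default 32, 64, 128, 256).
#' @param n_stages Encoder depth (default 4); must not exceed
#'   `length(channels)`.
#' @param down_ratio Fraction of points kept by each transition-down
#'   (default 0.25).
#' @param sigma_mode `"radius"` ties the attention distance scale to the
#'   effective radius of the neighbourhood's scale (keeps weights scale
#'   free); `"fixed"` uses `sigma_fixed` metres.
#' @param sigma_fixed Distance scale in metres when `sigma_mode = "fixed"`.
#' @param n_classes Number of semantic classes (default 2: leaf, stem).
#' @param ablation One of `"full"`, `"no_geometry_attention"`,
#'   `"no_multiscale"` (single mid-radius scale), `"baseline_pt"` (plain
#'   q/k/v self-attention layers only).
#' @param psi_dim Width of the learned positional embedding (default 8).
#' @param k_interp Nearest coarse points used by transition-up (default 3).
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(radii = c(0.05, 0.10, 0.15), max_neighbors = 32,
                       knn_k_attention = 16, channels = c(32, 64, 128, 256),
                       n_stages = 4, down_ratio = 0.25,
                       sigma_mode = c("radius", "fixed"), sigma_fixed = 0.1,
                       n_classes = 2,
                       ablation = c("full", "no_geometry_attention",
                                    "no_multiscale", "baseline_pt"),
                       psi_dim = 8, k_interp = 3) {
  sigma_mode <- match.arg(sigma_mode)
  ablation <- match.arg(ablation)
  if (length(radii) != 3 || any(diff(radii) <= 0) || any(radii <= 0)) {
    stop("`radii` must be three strictly increasing positive fractions",
         call. = FALSE)
  }
  stopifnot(down_ratio > 0, down_ratio < 1, n_classes >= 2,
            max_neighbors >= 1, knn_k_attention >= 1, psi_dim >= 1,
            k_interp >= 1)
  if (n_stages < 1 || n_stages > length(channels)) {
    stop("`n_stages` must be in [1, length(channels)]", call. = FALSE)
  }
  if (sigma_mode == "fixed" && sigma_fixed <= 0) {
    stop("`sigma_fixed` must be positive", call. = FALSE)
  }
  structure(list(radii = radii, max_neighbors = as.integer(max_neighbors),
                 knn_k_attention = as.integer(knn_k_attention),
                 channels = as.integer(channels),
                 n_stages = as.integer(n_stages), down_ratio = down_ratio,
                 sigma_mode = sigma_mode, sigma_fixed = sigma_fixed,
                 n_classes = as.integer(n_classes), ablation = ablation,
                 psi_dim = as.integer(psi_dim), k_interp = as.integer(k_interp)),
            class = "seg_config")
}

# ---------------------------------------------------------------------------
# Neighbourhood machinery (all geometry, no learned state)

#' Ball-query neighbourhoods
#'
#' For each center, up to `max_neighbors` points within `radius`,
#' nearest-first; the center itself is always included and an empty ball
#' falls back to the center alone.
#'
#' @param coords M x 3 matrix (or point-cloud data frame).
#' @param centers Integer indices of the query centers (rows of `coords`).
#' @param radius Ball radius in metres.
#' @param max_neighbors Cap on neighbours per center.
#' @return A `neighborhood_index`: flat pair vectors `center` and `neighbor`
#'   (1-based into `coords`), `center_pos` (position of each pair's center
#'   in `centers`), `dist`, `delta` (P x 3 offsets neighbor - center),
#'   `sizes`, `centers`, `n_ref`.
#' @export
ball_query <- function(coords, centers, radius, max_neighbors = 32L) {
  if (is.data.frame(coords)) coords <- cloud_coords(coords)
  res <- cpp_ball_query(coords, as.integer(centers), radius,
                        as.integer(max_neighbors))
  sizes <- lengths(res$idx)
  nbr <- unlist(res$idx, use.names = FALSE)
  ctr_pos <- rep(seq_along(centers), sizes)
  ctr <- centers[ctr_pos]
  structure(list(center = ctr, neighbor = nbr, center_pos = ctr_pos,
                 dist = unlist(res$dist, use.names = FALSE),
                 delta = coords[nbr, , drop = FALSE] -
                   coords[ctr, , drop = FALSE],
                 sizes = sizes, centers = centers, n_ref = nrow(coords)),
            class = "neighborhood_index")
}

# kNN neighbourhood (self included) in the same flat pair layout
knn_neighborhood <- function(coords, k) {
  m <- nrow(coords)
  if (m == 1) {
    return(structure(list(center = 1L, neighbor = 1L, center_pos = 1L,
                          dist = 0, delta = matrix(0, 1, 3), sizes = 1L,
                          centers = 1L, n_ref = 1L),
                     class = "neighborhood_index"))
  }
  k <- min(k, m - 1L)
  res <- cpp_knn(coords, k)
  ctr <- rep(seq_len(m), each = k + 1L)
  nbr <- as.integer(t(cbind(seq_len(m), res$idx)))
  d <- as.numeric(t(cbind(0, sqrt(res$d2))))
  structure(list(center = ctr, neighbor = nbr, center_pos = ctr, dist = d,
                 delta = coords[nbr, , drop = FALSE] -
                   coords[ctr, , drop = FALSE],
                 sizes = rep(k + 1L, m), centers = seq_len(m), n_ref = m),
            class = "neighborhood_index")
}

# softmax of -d/sigma within each center's pair group
distance_weights <- function(neigh, sigma) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  as.vector(.group_softmax(matrix(-neigh$dist / sigma, ncol = 1),
                           neigh$center_pos))
}

# sparse aggregator: rows = centers, cols = flat pairs
pair_aggregator <- function(neigh, weights) {
  Matrix::sparseMatrix(i = neigh$center_pos, j = seq_along(neigh$neighbor),
                       x = weights,
                       dims = c(length(neigh$centers), length(neigh$neighbor)))
}

# sparse mixing matrix: rows = centers, cols = reference points, so it can
# multiply a feature matrix directly (neighbour pairs are unique for kNN)
point_aggregator <- function(neigh, weights) {
  Matrix::sparseMatrix(i = neigh$center_pos, j = neigh$neighbor, x = weights,
                       dims = c(length(neigh$centers), neigh$n_ref))
}

#' Geometry-aware attention
#'
#' Attention weights are `softmax_j(-d_ij / sigma)` within each center's
#' neighbourhood, so nearer neighbours receive larger weights; the output
#' feature of a center is the weighted sum of its neighbours' raw features.
#'
#' @param neigh A [ball_query()] (or internal kNN) neighbourhood.
#' @param features M x C feature matrix aligned with the reference points of
#'   `neigh`.
#' @param sigma Positive distance scale in metres.
#' @return An `n_centers x C` matrix with the per-pair weights attached as
#'   attribute `"weights"`.
#' @export
geometry_attention <- function(neigh, features, sigma) {
  w <- distance_weights(neigh, sigma)
  A <- pair_aggregator(neigh, w)
  out <- .spmm(A, .gather(features, neigh$neighbor))
  attr(out, "weights") <- w
  out
}

#' Learned positional embedding of relative offsets
#'
#' A two-layer perceptron applied to `[dp; ||dp||]`, the offset from center
#' to neighbour and its norm, yielding one embedding row per pair.
#'
#' @param offsets P x 3 matrix of offsets `p_j - p_i`.
#' @param params List with `W1` (4 x H), `b1`, `W2` (H x H), `b2`.
#' @return P x H embedding matrix.
#' @export
positional_embedding <- function(offsets, params) {
  X <- cbind(offsets, sqrt(rowSums(offsets^2)))
  .linear(.relu(.linear(X, params$W1, params$b1)), params$W2, params$b2)
}

#' Multi-scale neighbourhood aggregation
#'
#' Per scale `s`, the message from neighbour `j` to center `i` is
#' `phi_s([f_j - f_i; psi_ij])`; messages are combined by an
#' attention-weighted sum whose weights are the distance kernel
#' `softmax_j(-d_ij / sigma_s)`, and the per-scale results are concatenated.
#'
#' @param features M x C features of the reference points.
#' @param neighborhoods List of `neighborhood_index`, one per scale.
#' @param params List with `psi` (positional-embedding params) and `phi`, a
#'   list (one per scale) of `W`/`b` for the shared message perceptron.
#' @param sigmas Distance scales, one per scale.
#' @return `n_centers x (n_scales * C_s)` feature matrix.
#' @export
multiscale_aggregate <- function(features, neighborhoods, params, sigmas) {
  if (length(neighborhoods) != length(params$phi) ||
      length(neighborhoods) != length(sigmas)) {
    stop("scale count mismatch between neighborhoods, phi params and sigmas",
         call. = FALSE)
  }
  hs <- lapply(seq_along(neighborhoods), function(s) {
    ng <- neighborhoods[[s]]
    fdiff <- .sub(.gather(features, ng$neighbor), .gather(features, ng$center))
    psi <- positional_embedding(ng$delta, params$psi)
    msg <- .relu(.linear(.cbind(fdiff, psi), params$phi[[s]]$W,
                         params$phi[[s]]$b))
    A <- pair_aggregator(ng, distance_weights(ng, sigmas[s]))
    .spmm(A, msg)
  })
  do.call(.cbind, hs)
}

#' Baseline point-transformer self-attention
#'
#' The plain self-attention layer: `q = Wq x`, `k = Wk x`, `v = Wv x`;
#' per-center weights are the softmax over neighbours of `q_i . k_j`, and
#' the output is the weighted sum of `v_j`. Used as the `baseline_pt`
#' ablation path.
#'
#' @param features M x C input features.
#' @param neigh A `neighborhood_index` over the same points.
#' @param params List with square matrices `Wq`, `Wk`, `Wv`.
#' @return `n_centers x C` attended features.
#' @export
baseline_self_attention <- function(features, neigh, params) {
  fv <- ad_val(features)
  if (ncol(ad_val(params$Wq)) != ncol(ad_val(params$Wk))) {
    stop("Wq and Wk output widths must agree", call. = FALSE)
  }
  if (ncol(fv) != nrow(ad_val(params$Wq))) {
    stop("feature width does not match Wq input width", call. = FALSE)
  }
  q <- .mm(features, params$Wq)
  k <- .mm(features, params$Wk)
  v <- .mm(features, params$Wv)
  logits <- .rowdot(.gather(q, neigh$center), .gather(k, neigh$neighbor))
  w <- .group_softmax(logits, neigh$center_pos)
  ones <- pair_aggregator(neigh, rep(1, length(neigh$neighbor)))
  .spmm(ones, .rowscale(.gather(v, neigh$neighbor), w))
}

#' Linear fusion of multi-scale and geometry-aware features
#'
#' Channel concatenation followed by a linear map.
#'
#' @param x_multi,x_geo Per-point feature matrices with equal row counts;
#'   `x_geo = NULL` fuses the multi-scale branch alone.
#' @param params List with `W` and `b`.
#' @return Fused feature matrix of width `ncol(W)`.
#' @export
fuse_features <- function(x_multi, x_geo, params) {
  if (!is.null(x_geo)) {
    if (nrow(ad_val(x_multi)) != nrow(ad_val(x_geo))) {
      stop("x_multi and x_geo must have matching point counts", call. = FALSE)
    }
    x <- .cbind(x_multi, x_geo)
  } else {
    x <- x_multi
  }
  .linear(x, params$W, params$b)
}

#' Transition down: FPS support + local max-pooling
#'
#' Selects a farthest-point-sampling support of `round(down_ratio * M)`
#' points (canonical start: the lexicographically smallest point, so the
#' operation is permutation-stable), transforms features with a linear+ReLU
#' perceptron, and max-pools them channel-wise over each support point's
#' ball neighbourhood.
#'
#' @param coords M x 3 coordinates of the current level.
#' @param features M x C features of the current level.
#' @param radius Pooling ball radius in metres.
#' @param down_ratio Fraction of points to keep, (0, 1].
#' @param params List with `W` (C x C') and `b`.
#' @param max_neighbors Cap on pooled neighbours.
#' @return List: `support` (indices into the parent level), `coords`,
#'   `features` (M' x C').
#' @export
transition_down <- function(coords, features, radius, down_ratio, params,
                            max_neighbors = 32L) {
  m <- nrow(coords)
  m2 <- max(1L, as.integer(round(down_ratio * m)))
  support <- farthest_point_sample(coords, m2, start = canonical_start(coords))
  ng <- ball_query(coords, support, radius, max_neighbors)
  rows <- split(seq_along(ng$neighbor), ng$center_pos)
  tf <- .relu(.linear(features, params$W, params$b))
  pooled <- .group_max(.gather(tf, ng$neighbor), rows)
  list(support = support, coords = coords[support, , drop = FALSE],
       features = pooled)
}

#' Transition up: inverse-distance feature interpolation
#'
#' Each fine point receives the weighted mean of its `k_interp` nearest
#' coarse points' features, weights proportional to `1 / (d^2 + 1e-8)` and
#' normalised to sum one, so a fine point coincident with a coarse point
#' recovers that coarse feature.
#'
#' @param coarse_coords,coarse_features The coarse level.
#' @param fine_coords M x 3 target coordinates.
#' @param k_interp Number of coarse neighbours (default 3).
#' @return M x C interpolated features.
#' @export
transition_up <- function(coarse_coords, coarse_features, fine_coords,
                          k_interp = 3) {
  if (nrow(coarse_coords) == 0) stop("coarse level is empty", call. = FALSE)
  U <- interp_matrix(coarse_coords, fine_coords, k_interp)
  .spmm(U, coarse_features)
}

interp_matrix <- function(coarse_coords, fine_coords, k_interp = 3) {
  k <- min(k_interp, nrow(coarse_coords))
  res <- cpp_cross_knn(fine_coords, coarse_coords, k)
  w <- 1 / (res$d2 + 1e-8)
  w <- w / rowSums(w)
  Matrix::sparseMatrix(i = rep(seq_len(nrow(fine_coords)), k),
                       j = as.vector(res$idx), x = as.vector(w),
                       dims = c(nrow(fine_coords), nrow(coarse_coords)))
}

# permutation-stable FPS start: the lexicographically smallest point
canonical_start <- function(coords) {
  order(coords[, 1], coords[, 2], coords[, 3])[1]
}

# ---------------------------------------------------------------------------
# Model assembly

he_init <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
}

encoder_scales <- function(config) {
  switch(config$ablation, no_multiscale = 2L, baseline_pt = integer(0), 1:3)
}

use_geometry <- function(config) {
  config$ablation %in% c("full", "no_multiscale")
}

#' Build the segmentation model
#'
#' Initialises all trainable parameters of the configured network
#' (deterministically from `seed`). Ablation switches change the
#' architecture: `no_multiscale` keeps only the mid-radius scale,
#' `no_geometry_attention` drops the geometry-attention branch and replaces
#' attention-weighted aggregation by plain means, `baseline_pt` uses plain
#' q/k/v self-attention blocks with no positional embedding, message
#' perceptrons or fusion maps.
#'
#' @param config A [seg_config()].
#' @param seed Integer seed for parameter initialisation.
#' @return A list of class `seg_model` with `config` and named `params`.
#' @export
build_model <- function(config = seg_config(), seed = 1L) {
  stopifnot(inherits(config, "seg_config"))
  S <- config$n_stages
  ch <- config$channels
  psi <- config$psi_dim
  P <- list()
  with_seed(seed, {
    P$embed_W <- he_init(3, ch[1]); P$embed_b <- matrix(0, 1, ch[1])
    for (l in seq_len(S)) {
      c_l <- ch[l]
      if (config$ablation == "baseline_pt") {
        P[[paste0("att", l, "_Wq")]] <- he_init(c_l, c_l)
        P[[paste0("att", l, "_Wk")]] <- he_init(c_l, c_l)
        P[[paste0("att", l, "_Wv")]] <- he_init(c_l, c_l)
      } else {
        P[[paste0("psi", l, "_W1")]] <- he_init(4, psi)
        P[[paste0("psi", l, "_b1")]] <- matrix(0, 1, psi)
        P[[paste0("psi", l, "_W2")]] <- he_init(psi, psi)
        P[[paste0("psi", l, "_b2")]] <- matrix(0, 1, psi)
        for (s in encoder_scales(config)) {
          P[[paste0("phi", l, "_", s, "_W")]] <- he_init(c_l + psi, c_l)
          P[[paste0("phi", l, "_", s, "_b")]] <- matrix(0, 1, c_l)
        }
        in_fuse <- length(encoder_scales(config)) * c_l +
          if (use_geometry(config)) c_l else 0L
        P[[paste0("fuse", l, "_W")]] <- he_init(in_fuse, c_l)
        P[[paste0("fuse", l, "_b")]] <- matrix(0, 1, c_l)
      }
      if (l < S) {
        P[[paste0("td", l, "_W")]] <- he_init(c_l, ch[l + 1])
        P[[paste0("td", l, "_b")]] <- matrix(0, 1, ch[l + 1])
      }
    }
    for (l in rev(seq_len(S - 1))) {
      P[[paste0("dec", l, "_W")]] <- he_init(ch[l] + ch[l + 1], ch[l])
      P[[paste0("dec", l, "_b")]] <- matrix(0, 1, ch[l])
    }
    P$head_W1 <- he_init(ch[1], ch[1]); P$head_b1 <- matrix(0, 1, ch[1])
    P$head_W2 <- he_init(ch[1], config$n_classes)
    P$head_b2 <- matrix(0, 1, config$n_classes)
  })
  structure(list(config = config, params = P), class = "seg_model")
}

#' Number of trainable parameters of a model
#'
#' @param model A [build_model()] result.
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cat("Point-transformer segmentation model\n")
  cat("  stages:", x$config$n_stages,
      " channels:", paste(x$config$channels[seq_len(x$config$n_stages)],
                          collapse = "/"),
      " ablation:", x$config$ablation, "\n")
  cat("  trainable parameters:", n_parameters(x), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Pyramid precomputation: every quantity that depends on geometry alone.
# Cached per cloud and reused across epochs; the attention weights are
# invariant under the package's augmentations (translation, XZ flip, and
# isotropic scaling, since radii and sigma are height-normalized).

build_pyramid <- function(coords, config) {
  n <- nrow(coords)
  height <- diff(range(coords[, 3]))
  if (height <= 0) height <- max(diff(range(coords[, 1])),
                                 diff(range(coords[, 2])), 1e-6)
  growth <- 1 / sqrt(config$down_ratio)   # keeps neighbour counts stable
  levels <- list()
  cur <- coords
  orig_idx <- seq_len(n)
  for (l in seq_len(config$n_stages)) {
    m <- nrow(cur)
    r_eff <- config$radii * height * growth^(l - 1)
    lev <- list(coords = cur, orig_idx = orig_idx, r_eff = r_eff)
    if (config$ablation == "baseline_pt") {
      lev$att <- knn_neighborhood(cur, config$knn_k_attention)
    } else {
      scales <- encoder_scales(config)
      lev$balls <- lapply(scales, function(s) {
        ball_query(cur, seq_len(m), r_eff[s], config$max_neighbors)
      })
      lev$sigmas <- vapply(scales, function(s) {
        if (config$sigma_mode == "radius") r_eff[s] else config$sigma_fixed
      }, numeric(1))
      lev$aggs <- lapply(seq_along(scales), function(k) {
        pair_aggregator(lev$balls[[k]],
                        distance_weights(lev$balls[[k]], lev$sigmas[k]))
      })
      att <- knn_neighborhood(cur, config$knn_k_attention)
      sig_att <- if (config$sigma_mode == "radius") r_eff[2] else config$sigma_fixed
      lev$A_att <- point_aggregator(att, distance_weights(att, sig_att))
      lev$A_mean <- point_aggregator(att, 1 / rep(att$sizes, att$sizes))
    }
    if (is.null(lev$A_mean)) {   # baseline path still needs mean mixing
      att <- lev$att
      lev$A_mean <- point_aggregator(att, 1 / rep(att$sizes, att$sizes))
    }
    if (l < config$n_stages) {
      m2 <- max(1L, as.integer(round(config$down_ratio * m)))
      support <- farthest_point_sample(cur, m2, start = canonical_start(cur))
      ngp <- ball_query(cur, support, r_eff[2], config$max_neighbors)
      lev$pool_rows <- split(seq_along(ngp$neighbor), ngp$center_pos)
      lev$pool_gather <- ngp$neighbor
      lev$support <- support
      nxt <- cur[support, , drop = FALSE]
      lev$up <- interp_matrix(nxt, cur, config$k_interp)
      levels[[l]] <- lev
      orig_idx <- orig_idx[support]
      cur <- nxt
    } else {
      levels[[l]] <- lev
    }
  }
  list(levels = levels, height = height, n = n)
}

# Forward pass over (possibly tape-lifted) parameters. `coords_aug` are the
# augmented coordinates of the *original* cloud; geometry (neighbour sets,
# attention weights) always comes from the cached pyramid.
forward_scores <- function(P, config, pyramid, coords_aug) {
  ctr <- colMeans(coords_aug)
  h_aug <- diff(range(coords_aug[, 3]))
  if (h_aug <= 0) h_aug <- 1
  f <- sweep(coords_aug, 2, ctr) / h_aug
  f <- .relu(.linear(f, P$embed_W, P$embed_b))
  S <- config$n_stages
  skips <- vector("list", S)
  for (l in seq_len(S)) {
    lev <- pyramid$levels[[l]]
    aug_l <- coords_aug[lev$orig_idx, , drop = FALSE]
    if (config$ablation == "baseline_pt") {
      f <- baseline_self_attention(f, lev$att,
                                   list(Wq = P[[paste0("att", l, "_Wq")]],
                                        Wk = P[[paste0("att", l, "_Wk")]],
                                        Wv = P[[paste0("att", l, "_Wv")]]))
    } else {
      scales <- encoder_scales(config)
      psi_par <- list(W1 = P[[paste0("psi", l, "_W1")]],
                      b1 = P[[paste0("psi", l, "_b1")]],
                      W2 = P[[paste0("psi", l, "_W2")]],
                      b2 = P[[paste0("psi", l, "_b2")]])
      hs <- lapply(seq_along(scales), function(k) {
        ng <- lev$balls[[k]]
        delta <- aug_l[ng$neighbor, , drop = FALSE] -
          aug_l[ng$center, , drop = FALSE]
        fdiff <- .sub(.gather(f, ng$neighbor), .gather(f, ng$center))
        psi <- positional_embedding(delta, psi_par)
        msg <- .relu(.linear(.cbind(fdiff, psi),
                             P[[paste0("phi", l, "_", scales[k], "_W")]],
                             P[[paste0("phi", l, "_", scales[k], "_b")]]))
        .spmm(lev$aggs[[k]], msg)
      })
      x_multi <- if (length(hs) == 1) hs[[1]] else do.call(.cbind, hs)
      x_geo <- if (use_geometry(config)) .spmm(lev$A_att, f) else NULL
      f <- .relu(fuse_features(x_multi, x_geo,
                               list(W = P[[paste0("fuse", l, "_W")]],
                                    b = P[[paste0("fuse", l, "_b")]])))
    }
    skips[[l]] <- f
    if (l < S) {
      tf <- .relu(.linear(f, P[[paste0("td", l, "_W")]],
                          P[[paste0("td", l, "_b")]]))
      f <- .group_max(.gather(tf, pyramid$levels[[l]]$pool_gather),
                      pyramid$levels[[l]]$pool_rows)
    }
  }
  for (l in rev(seq_len(S - 1))) {
    lev <- pyramid$levels[[l]]
    up <- .spmm(lev$up, f)
    f <- .relu(.linear(.cbind(up, skips[[l]]),
                       P[[paste0("dec", l, "_W")]],
                       P[[paste0("dec", l, "_b")]]))
    mixer <- if (use_geometry(config)) lev$A_att else lev$A_mean
    f <- .spmm(mixer, f)
  }
  .linear(.relu(.linear(f, P$head_W1, P$head_b1)), P$head_W2, P$head_b2)
}

#' Segment a point cloud with a model
#'
#' Runs the forward pass in inference mode and returns the input cloud with
#' per-class scores and the predicted label appended. Deterministic for
#' fixed parameters: the internal samplers use a canonical start derived
#' from the coordinates, so the result is stable under point reordering.
#'
#' @param model A [build_model()] (possibly trained) model.
#' @param cloud A point-cloud data frame.
#' @param pyramid Optional precomputed neighbourhood pyramid (internal use).
#' @return The cloud tibble plus `score_leaf`, `score_stem`, ... and
#'   `pred_label` columns.
#' @export
forward_segment <- function(model, cloud, pyramid = NULL) {
  validate_point_cloud(cloud)
  coords <- cloud_coords(cloud)
  min_n <- ceiling((1 / model$config$down_ratio)^(model$config$n_stages - 1))
  if (nrow(coords) < min_n) {
    stop("cloud has ", nrow(coords), " points but the ", model$config$n_stages,
         "-stage pyramid needs at least ", min_n,
         "; use fewer stages (smaller `n_stages`)", call. = FALSE)
  }
  if (is.null(pyramid)) pyramid <- build_pyramid(coords, model$config)
  scores <- forward_scores(model$params, model$config, pyramid, coords)
  out <- tibble::as_tibble(cloud)
  cls_names <- if (model$config$n_classes == 2) c("leaf", "stem")
               else paste0("class", seq_len(model$config$n_classes) - 1L)
  for (k in seq_len(model$config$n_classes)) {
    out[[paste0("score_", cls_names[k])]] <- scores[, k]
  }
  out$pred_label <- max.col(scores, ties.method = "first") - 1L
  new_point_cloud(out, name = attr(cloud, "name"))
}

#' Save / load a model checkpoint
#'
#' Single-file, versioned container holding the configuration and all named
#' parameter blocks.
#'
#' @param model A `seg_model`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `seg_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(list(schema = "stemleaf-checkpoint", version = 1L,
               config = model$config, params = model$params,
               history = model$history), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "stemleaf-checkpoint")) {
    stop("not a stemleaf checkpoint: ", path, call. = FALSE)
  }
  structure(list(config = obj$config, params = obj$params,
                 history = obj$history), class = "seg_model")
}
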