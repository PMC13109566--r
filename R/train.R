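#' Training configuration
#'
#' Defaults follow the protocol the package targets: AdamW with initial
#' learning rate 0.003, batch size 2, a learning-rate decay schedule
#' (cosine by default), weighted cross-entropy with inverse-frequency
#' class weights (stems are the minority class), and early stopping when
#' the validation loss stops improving.
#'
#' @param learning_rate Initial learning rate (> 0, default 0.003).
#' @param batch_size Clouds per optimiser step (default 2).
#' @param lr_decay `"cosine"` annealing over `max_epochs` or `"step"`
#'   (halving every `max_epochs / 4` epochs).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping (default 20).
#' @param min_delta Minimum loss decrease counted as improvement.
#' @param max_epochs Epoch budget (default 100).
#' @param weight_decay AdamW decoupled weight decay (default 0.01).
#' @param class_weights `"inverse_frequency"` or `"uniform"`.
#' @param stop_at_train_macc Optional percentage; stop as soon as the
#'   training-pass mean class accuracy reaches it (used by overfitting
#'   harnesses).
#' @param seed Integer seed for shuffling and augmentation draws.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.003, batch_size = 2,
                         lr_decay = c("cosine", "step"),
                         early_stop_patience = 20, min_delta = 1e-4,
                         max_epochs = 100, weight_decay = 0.01,
                         class_weights = c("inverse_frequency", "uniform"),
                         stop_at_train_macc = NULL, seed = 1L) {
  lr_decay <- match.arg(lr_decay)
  class_weights <- match.arg(class_weights)
  stopifnot(learning_rate > 0, batch_size >= 1, early_stop_patience >= 1,
            max_epochs >= 1, weight_decay >= 0, min_delta >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), lr_decay = lr_decay,
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay, class_weights = class_weights,
                 stop_at_train_macc = stop_at_train_macc,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split a dataset manifest
#'
#' `holdout_cultivar` reserves one cultivar's full growth cycle for the
#' test set and a second cultivar for validation, training on the rest;
#' `holdout_plant` does the same at the level of individual plants (the
#' protocol used for day-indexed maize/tomato series). Deterministic per
#' seed; the splits partition the manifest.
#'
#' @param manifest A tibble with one row per cloud and a `cultivar` (or
#'   `plant`) column.
#' @param scheme `"holdout_cultivar"` or `"holdout_plant"`.
#' @param seed Integer seed choosing the held-out units.
#' @return A list of manifests: `train`, `val`, `test`.
#' @export
split_dataset <- function(manifest, scheme = c("holdout_cultivar",
                                               "holdout_plant"),
                          seed = 1L) {
  scheme <- match.arg(scheme)
  unit <- if (scheme == "holdout_cultivar") "cultivar" else "plant"
  if (!unit %in% names(manifest)) {
    stop("manifest lacks a `", unit, "` column", call. = FALSE)
  }
  units <- sort(unique(manifest[[unit]]))
  if (length(units) < 3) {
    stop("need at least 3 distinct ", unit, "s to split; got ",
         length(units), call. = FALSE)
  }
  held <- with_seed(seed, sample(units, 2))
  list(train = manifest[!manifest[[unit]] %in% held, , drop = FALSE],
       val = manifest[manifest[[unit]] == held[2], , drop = FALSE],
       test = manifest[manifest[[unit]] == held[1], , drop = FALSE])
}

manifest_clouds <- function(manifest) {
  if ("cloud" %in% names(manifest)) return(manifest$cloud)
  if (!"path" %in% names(manifest)) {
    stop("manifest needs a `cloud` or `path` column", call. = FALSE)
  }
  lapply(manifest$path, read_point_cloud)
}

class_weight_vector <- function(labels, mode, n_classes) {
  if (mode == "uniform") return(rep(1, n_classes))
  freq <- tabulate(labels + 1L, nbins = n_classes)
  w <- sum(freq) / pmax(freq, 1) / n_classes
  w / mean(w)
}

adamw_step <- function(params, grads, state, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * (step + wd * params[[nm]])
  }
  list(params = params, state = state)
}

epoch_lr <- function(config, epoch) {
  base <- config$learning_rate
  switch(config$lr_decay,
    cosine = base * 0.5 * (1 + cos(pi * (epoch - 1) / config$max_epochs)),
    step = base * 0.5^((epoch - 1) %/% max(1, config$max_epochs %/% 4))
  )
}

#' Train a segmentation model
#'
#' Minimises weighted cross-entropy over per-point labels with AdamW,
#' applying the enabled augmentations per epoch, recording per-epoch
#' training/validation loss and validation mIoU/mAcc, and stopping early
#' when the monitored loss (validation if available, else training) fails
#' to improve by `min_delta` for `early_stop_patience` epochs. The
#' neighbourhood pyramid of every cloud is precomputed once and reused
#' across epochs (the package's augmentations leave neighbour sets and
#' attention weights unchanged). Returns the best-validation model.
#'
#' @param model A [build_model()] model.
#' @param train_manifest,val_manifest Manifest tibbles with `cloud` or
#'   `path` columns; `val_manifest = NULL` monitors the training loss.
#' @param config A [train_config()].
#' @param augment An [augment_config()], or `NULL` to disable augmentation.
#' @param verbose Print a line per epoch.
#' @return The trained `seg_model` with a `history` tibble (epoch, lr,
#'   train_loss, val_loss, val_miou, val_macc) attached.
#' @export
train_model <- function(model, train_manifest, val_manifest = NULL,
                        config = train_config(), augment = augment_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  if (!nrow(train_manifest)) stop("empty training manifest", call. = FALSE)
  tr_clouds <- manifest_clouds(train_manifest)
  va_clouds <- if (!is.null(val_manifest) && nrow(val_manifest))
    manifest_clouds(val_manifest) else NULL
  for (cl in c(tr_clouds, va_clouds)) {
    if (!has_labels(cl)) stop("all clouds must be labelled for training",
                              call. = FALSE)
  }
  tr_pyr <- lapply(tr_clouds, function(cl)
    build_pyramid(cloud_coords(cl), model$config))
  va_pyr <- if (!is.null(va_clouds))
    lapply(va_clouds, function(cl) build_pyramid(cloud_coords(cl), model$config))
  all_labels <- unlist(lapply(tr_clouds, function(cl) cl$label))
  cw <- class_weight_vector(all_labels, config$class_weights,
                            model$config$n_classes)

  params <- model$params
  state <- new.env(parent = emptyenv())
  state$t <- 0L
  state$m <- lapply(params, function(p) p * 0)
  state$v <- lapply(params, function(p) p * 0)

  history <- list()
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  n_tr <- length(tr_clouds)

  eval_loss <- function(clouds, pyrs) {
    losses <- vapply(seq_along(clouds), function(i) {
      sc <- forward_scores(params, model$config, pyrs[[i]],
                           cloud_coords(clouds[[i]]))
      .ce_loss(sc, clouds[[i]]$label, cw)
    }, numeric(1))
    mean(losses)
  }
  eval_metrics <- function(clouds, pyrs) {
    ms <- purrr::map_dfr(seq_along(clouds), function(i) {
      sc <- forward_scores(params, model$config, pyrs[[i]],
                           cloud_coords(clouds[[i]]))
      pred <- max.col(sc, ties.method = "first") - 1L
      segmentation_metrics(clouds[[i]]$label, pred, model$config$n_classes)
    })
    dplyr::summarise(ms, dplyr::across(dplyr::everything(), mean))
  }

  for (epoch in seq_len(config$max_epochs)) {
    lr <- epoch_lr(config, epoch)
    ord <- with_seed(config$seed + epoch, sample.int(n_tr))
    batch_losses <- c()
    epoch_maccs <- numeric(0)
    b <- 1L
    while (b <= n_tr) {
      ids <- ord[b:min(b + config$batch_size - 1L, n_tr)]
      grads_acc <- NULL
      loss_acc <- 0
      for (i in ids) {
        cl <- tr_clouds[[i]]
        aug_seed <- config$seed + 7919L * epoch + 13L * i
        cl_aug <- apply_augmentations(cl, augment, aug_seed)
        tape <- ad_tape()
        P <- lapply(stats::setNames(names(params), names(params)),
                    function(nm) ad_param(tape, params[[nm]], nm))
        sc <- forward_scores(P, model$config, tr_pyr[[i]],
                             cloud_coords(cl_aug))
        loss <- .ce_loss(sc, cl$label, cw)
        lv <- ad_val(loss)[1]
        if (!is.finite(lv)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               " (cloud ", i, "); lower the learning rate", call. = FALSE)
        }
        loss_acc <- loss_acc + lv
        pred <- max.col(ad_val(sc), ties.method = "first") - 1L
        epoch_maccs <- c(epoch_maccs,
                         segmentation_metrics(cl$label, pred,
                                              model$config$n_classes)$macc)
        g <- ad_backward(loss)
        grads_acc <- if (is.null(grads_acc)) g else {
          for (nm in names(g)) grads_acc[[nm]] <- grads_acc[[nm]] + g[[nm]]
          grads_acc
        }
      }
      grads_acc <- lapply(grads_acc, function(g) g / length(ids))
      upd <- adamw_step(params, grads_acc, state, lr, config$weight_decay)
      params <- upd$params
      batch_losses <- c(batch_losses, loss_acc / length(ids))
      b <- b + config$batch_size
    }
    train_loss <- mean(batch_losses)
    train_macc <- mean(epoch_maccs)
    if (!is.null(va_clouds)) {
      val_loss <- eval_loss(va_clouds, va_pyr)
      vm <- eval_metrics(va_clouds, va_pyr)
      val_miou <- vm$miou
      val_macc <- vm$macc
    } else {
      val_loss <- NA_real_
      val_miou <- NA_real_
      val_macc <- NA_real_
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, lr = lr,
                                       train_loss = train_loss,
                                       train_macc = train_macc,
                                       val_loss = val_loss,
                                       val_miou = val_miou,
                                       val_macc = val_macc)
    if (!is.null(config$stop_at_train_macc) &&
        train_macc >= config$stop_at_train_macc) {
      best <- list(loss = if (is.na(val_loss)) train_loss else val_loss,
                   params = params, epoch = epoch)
      break
    }
    if (verbose) {
      message(sprintf("epoch %3d lr %.5f train %.4f val %s", epoch, lr,
                      train_loss,
                      if (is.na(val_loss)) "-" else sprintf("%.4f", val_loss)))
    }
    monitored <- if (is.na(val_loss)) train_loss else val_loss
    if (monitored < best$loss - config$min_delta) {
      best <- list(loss = monitored, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  out <- model
  out$params <- best$params
  out$history <- dplyr::bind_rows(history)
  out$best_epoch <- best$epoch
  out$class_weights <- cw
  out
}

#' Evaluate a model over a manifest
#'
#' Segments every (labelled) cloud and computes per-cloud metrics plus the
#' unweighted macro-average across clouds.
#'
#' @param model A trained `seg_model`.
#' @param manifest Manifest tibble with `cloud` or `path` columns.
#' @return A list of class `seg_evaluation`: `per_cloud` (one metrics row
#'   per cloud) and `aggregate` (their unweighted mean).
#' @export
evaluate_model <- function(model, manifest) {
  clouds <- manifest_clouds(manifest)
  for (i in seq_along(clouds)) {
    if (!has_labels(clouds[[i]])) {
      stop("cloud ", attr(clouds[[i]], "name") %||% i,
           " has no labels; cannot evaluate", call. = FALSE)
    }
  }
  per <- purrr::map_dfr(seq_along(clouds), function(i) {
    seg <- forward_segment(model, clouds[[i]])
    m <- segmentation_metrics(clouds[[i]]$label, seg$pred_label,
                              model$config$n_classes)
    dplyr::bind_cols(tibble::tibble(cloud = attr(clouds[[i]], "name") %||%
                                      as.character(i)), m)
  })
  agg <- dplyr::summarise(per, dplyr::across(dplyr::where(is.numeric), mean))
  structure(list(per_cloud = per, aggregate = agg), class = "seg_evaluation")
}

#' @export
print.seg_evaluation <- function(x, ...) {
  cat("Segmentation evaluation over", nrow(x$per_cloud), "clouds\n")
  print(x$aggregate)
  invisible(x)
}

#' Tidy methods for fitted models and evaluations
#'
#' `tidy()` on a trained model returns its per-epoch history; `glance()` a
#' one-row fit summary. On an evaluation, `tidy()` returns per-cloud
#' metrics and `glance()` the macro-average.
#'
#' @param x A `seg_model` or `seg_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.seg_model <- function(x, ...) {
  x$history %||% tibble::tibble()
}

#' @rdname tidy.seg_model
#' @export
glance.seg_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_parameters = n_parameters(x),
    n_stages = x$config$n_stages,
    ablation = x$config$ablation,
    epochs_trained = if (is.null(h)) 0L else nrow(h),
    best_epoch = x$best_epoch %||% NA_integer_,
    final_train_loss = if (is.null(h)) NA_real_ else h$train_loss[nrow(h)],
    best_val_loss = if (is.null(h) || all(is.na(h$val_loss))) NA_real_
                    else min(h$val_loss, na.rm = TRUE)
  )
}

#' @rdname tidy.seg_model
#' @export
tidy.seg_evaluation <- function(x, ...) x$per_cloud

#' @rdname tidy.seg_model
#' @export
glance.seg_evaluation <- function(x, ...) x$aggregate
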