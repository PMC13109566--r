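test_that("augmentations are label-preserving seeded isometries/similarities", {
  cl <- desk_clouds(1, seed0 = 60, n_points = 120)[[1]]
  d0 <- dist(cloud_coords(cl))

  expect_equal(center_shift(cl, 0, seed = 1), cl)
  sh <- center_shift(cl, 0.5, seed = 2)
  expect_equal(sh$label, cl$label)
  expect_equal(as.numeric(dist(cloud_coords(sh))), as.numeric(d0))
  expect_equal(center_shift(cl, 0.5, seed = 2), sh)

  expect_equal(random_scale(cl, 1, 1, seed = 1), cl)
  sc <- random_scale(cl, 2, 2, seed = 1)   # forced s = 2
  expect_equal(as.numeric(dist(cloud_coords(sc))), 2 * as.numeric(d0),
               tolerance = 1e-12)

  fl <- random_flip_xz(cl, force = TRUE)
  expect_equal(random_flip_xz(fl, force = TRUE), cl, tolerance = 1e-12)
  expect_equal(fl$x, cl$x)
  expect_equal(fl$z, cl$z)
  cy <- mean(cl$y)
  expect_equal(fl$y - cy, -(cl$y - cy), tolerance = 1e-12)
  expect_equal(as.numeric(dist(cloud_coords(fl))), as.numeric(d0),
               tolerance = 1e-10)
  expect_equal(fl$label, cl$label)
})

test_that("confusion counts follow the one-vs-rest definition", {
  truth <- c(rep(0L, 5), rep(1L, 5))
  cc <- confusion_counts(truth, truth)
  expect_equal(cc$fp, c(0L, 0L))
  expect_equal(cc$fn, c(0L, 0L))
  expect_true(all(cc$tp + cc$tn + cc$fp + cc$fn == 10))

  all_leaf <- confusion_counts(truth, rep(0L, 10))
  expect_equal(unlist(all_leaf[1, c("tp", "fp", "fn", "tn")]),
               c(tp = 5L, fp = 5L, fn = 0L, tn = 0L))

  swapped <- confusion_counts(rep(0L, 10), truth)
  expect_equal(swapped$fp, all_leaf$fn)
  expect_equal(swapped$fn, all_leaf$fp)
  expect_error(confusion_counts(1:3 * 0L, 0L), "equal length")
})

test_that("metrics match a brute-force confusion oracle on random labels", {
  for (case in 1:100) {
    withr::with_seed(1000 + case, {
      n <- sample(5:200, 1)
      truth <- sample(0:1, n, replace = TRUE)
      pred <- sample(0:1, n, replace = TRUE)
    })
    # independent oracle from the raw definitions
    oracle <- function(cl) {
      tp <- sum(truth == cl & pred == cl); fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl); tn <- n - tp - fp - fn
      c(acc = 100 * (tp + tn) / n,
        iou = if (tp + fp + fn > 0) 100 * tp / (tp + fp + fn) else NA)
    }
    o0 <- oracle(0); o1 <- oracle(1)
    m <- suppressWarnings(segmentation_metrics(truth, pred))
    if (!anyNA(c(o0, o1))) {
      expect_identical(m$acc_leaf, o0[["acc"]])
      expect_identical(m$iou_stem, o1[["iou"]])
      expect_identical(m$miou, (o0[["iou"]] + o1[["iou"]]) / 2)
      expect_identical(m$macc, (o0[["acc"]] + o1[["acc"]]) / 2)
    }
  }
})

test_that("metrics are symmetric under a joint label swap and handle
           vacuous classes", {
  withr::with_seed(2, {
    truth <- sample(0:1, 50, replace = TRUE)
    pred <- sample(0:1, 50, replace = TRUE)
  })
  m1 <- segmentation_metrics(truth, pred)
  m2 <- segmentation_metrics(1L - truth, 1L - pred)
  expect_equal(m1$macc, m2$macc)
  expect_equal(m1$miou, m2$miou)

  expect_warning(mv <- segmentation_metrics(rep(0L, 4), rep(0L, 4)),
                 "vacuous")
  expect_equal(mv$iou_stem, 100)
  expect_equal(mv$miou, 100)
})

test_that("dataset splitting holds out whole cultivars deterministically", {
  manifest <- generate_dataset(n_cultivars = 5, stages = c(2, 6),
                               plants_per_cell = 1, seed = 3, dir = NULL,
                               points_per_area = 5e3)
  expect_equal(nrow(manifest), 10)
  sp <- split_dataset(manifest, seed = 4)
  expect_length(unique(sp$test$cultivar), 1)
  expect_length(unique(sp$val$cultivar), 1)
  expect_length(intersect(sp$test$cultivar, sp$train$cultivar), 0)
  expect_equal(nrow(sp$train) + nrow(sp$val) + nrow(sp$test), nrow(manifest))
  sp2 <- split_dataset(manifest, seed = 4)
  expect_identical(sp$test$seed, sp2$test$seed)
  expect_error(split_dataset(manifest[manifest$cultivar < 3, ]), "at least 3")

  manifest$plant <- manifest$cultivar
  sp3 <- split_dataset(manifest, scheme = "holdout_plant", seed = 1)
  expect_length(unique(sp3$test$plant), 1)
})

test_that("one training epoch runs, descends, and early stopping triggers", {
  clouds <- desk_clouds(4, seed0 = 70, n_points = 150)
  tr <- tibble::tibble(cloud = clouds[1:3])
  va <- tibble::tibble(cloud = clouds[4])
  m <- build_model(desk_config(), seed = 5)

  smoke <- train_model(m, tr[1:2, ], NULL,
                       train_config(max_epochs = 1, seed = 1), augment = NULL)
  expect_equal(nrow(smoke$history), 1)
  expect_true(is.finite(smoke$history$train_loss))

  fit <- train_model(m, tr, va,
                     train_config(max_epochs = 15, early_stop_patience = 15,
                                  seed = 1), augment = NULL)
  h <- fit$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))

  # frozen model (lr ~ 0): patience of 1 stops after two epochs
  frozen <- train_model(m, tr[1:2, ], va,
                        train_config(learning_rate = 1e-12, max_epochs = 50,
                                     early_stop_patience = 1, seed = 1),
                        augment = NULL)
  expect_lte(nrow(frozen$history), 3)
})

test_that("evaluation reports per-cloud metrics and their unweighted mean", {
  clouds <- desk_clouds(3, seed0 = 80, n_points = 140)
  manifest <- tibble::tibble(cloud = clouds)
  m <- build_model(desk_config(), seed = 6)
  ev <- evaluate_model(m, manifest)
  expect_equal(nrow(ev$per_cloud), 3)
  expect_equal(ev$aggregate$miou, mean(ev$per_cloud$miou))
  expect_true(all(ev$per_cloud$macc >= 0 & ev$per_cloud$macc <= 100))
  expect_identical(tidy(ev), ev$per_cloud)
  expect_identical(glance(ev), ev$aggregate)

  unl <- manifest
  unl$cloud[[2]] <- point_cloud(cloud_coords(clouds[[2]]))
  expect_error(evaluate_model(m, unl), "labels")
})

test_that("ground truth evaluated as prediction scores 100 everywhere", {
  cl <- desk_clouds(1, seed0 = 90, n_points = 100)[[1]]
  m <- segmentation_metrics(cl$label, cl$label)
  expect_equal(m$miou, 100)
  expect_equal(m$macc, 100)
  expect_equal(m$iou_leaf, 100)
})
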