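#' One-vs-rest confusion counts
#'
#' For each class, the true/false positive/negative counts of the
#' one-vs-rest problem on the same N points, so `TP + TN + FP + FN = N`
#' for every class.
#'
#' @param truth,prediction Integer label vectors of equal length with values
#'   in `0 .. n_classes - 1`.
#' @param n_classes Number of classes (default 2).
#' @return A tibble with one row per class: `class`, `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, prediction, n_classes = 2) {
  if (length(truth) != length(prediction)) {
    stop("`truth` and `prediction` must have equal length", call. = FALSE)
  }
  if (!length(truth)) stop("empty label vectors", call. = FALSE)
  classes <- 0:(n_classes - 1)
  if (!all(truth %in% classes) || !all(prediction %in% classes)) {
    stop("labels outside 0..", n_classes - 1, call. = FALSE)
  }
  purrr::map_dfr(classes, function(cl) {
    tibble::tibble(class = cl,
                   tp = sum(truth == cl & prediction == cl),
                   tn = sum(truth != cl & prediction != cl),
                   fp = sum(truth != cl & prediction == cl),
                   fn = sum(truth == cl & prediction != cl))
  })
}

#' Segmentation metrics from confusion counts
#'
#' Per-class accuracy `(TP + TN) / N` and intersection-over-union
#' `TP / (TP + FP + FN)`, plus their two-class means `mAcc` and `mIoU`,
#' all reported as percentages. The IoU of a class absent from both truth
#' and prediction is vacuously 100 (with a warning).
#'
#' @param counts A [confusion_counts()] tibble (classes 0 = leaf, 1 = stem
#'   for the two-class task).
#' @return A one-row tibble: `acc_leaf`, `acc_stem`, `iou_leaf`, `iou_stem`,
#'   `macc`, `miou` (for two classes; generic `acc_k`/`iou_k` otherwise).
#' @export
compute_metrics <- function(counts) {
  n <- counts$tp[1] + counts$tn[1] + counts$fp[1] + counts$fn[1]
  if (is.na(n) || n == 0) stop("confusion counts sum to zero", call. = FALSE)
  acc <- 100 * (counts$tp + counts$tn) / n
  denom <- counts$tp + counts$fp + counts$fn
  iou <- ifelse(denom > 0, 100 * counts$tp / denom, NA_real_)
  if (anyNA(iou)) {
    warning("class absent from both truth and prediction; its IoU is vacuously 100")
    iou[is.na(iou)] <- 100
  }
  nm <- if (nrow(counts) == 2) c("leaf", "stem") else as.character(counts$class)
  out <- tibble::tibble(.rows = 1)
  for (k in seq_along(nm)) out[[paste0("acc_", nm[k])]] <- acc[k]
  for (k in seq_along(nm)) out[[paste0("iou_", nm[k])]] <- iou[k]
  out$macc <- mean(acc)
  out$miou <- mean(iou)
  out
}

#' Metrics directly from label vectors
#'
#' Convenience wrapper: [confusion_counts()] then [compute_metrics()].
#'
#' @inheritParams confusion_counts
#' @return The [compute_metrics()] tibble.
#' @export
segmentation_metrics <- function(truth, prediction, n_classes = 2) {
  compute_metrics(confusion_counts(truth, prediction, n_classes))
}
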