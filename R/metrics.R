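# Pixel-wise, ROI-scoped evaluation: one-vs-rest confusion counting, the
# scalar metrics computed from it, and threshold-sweep ROC-AUC. A true
# positive is a pixel inside the ROI predicted as the evaluated occlusion
# class whose ground truth is that class; all counting is per pixel.

#' One-vs-rest confusion table over an ROI
#'
#' @param pred,truth [label_mask()]s of one extent.
#' @param roi Logical matrix selecting the evaluated pixels, or `NULL` for
#'   the full frame. Must select at least one pixel.
#' @param class_id Class evaluated one-vs-rest (default 1, the occlusion
#'   class of a binary task).
#' @return A `confusion_table`: list with `class_id` and pixel counts `tp`,
#'   `fp`, `tn`, `fn`, which always sum to the ROI size.
#' @export
confusion <- function(pred, truth, roi = NULL, class_id = 1L) {
  if (!all(dim(pred) == dim(truth)))
    stopf("pred %dx%d and truth %dx%d differ in extent",
          nrow(pred), ncol(pred), nrow(truth), ncol(truth))
  if (is.null(roi)) roi <- matrix(TRUE, nrow(pred), ncol(pred))
  if (!all(dim(roi) == dim(pred))) stopf("roi extent mismatch")
  roi <- roi != 0
  if (!any(roi)) stopf("empty ROI")
  p <- pred[roi] == class_id
  t <- truth[roi] == class_id
  structure(list(class_id = as.integer(class_id),
                 tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  cat(sprintf("<confusion_table> class %d: tp=%d fp=%d tn=%d fn=%d\n",
              x$class_id, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Scalar metrics from a confusion table
#'
#' Accuracy `(tp+tn)/total`, precision `tp/(tp+fp)`, recall `tp/(tp+fn)`,
#' F1 (harmonic mean of precision and recall) and IoU `tp/(tp+fp+fn)`.
#' Undefined ratios (0/0) are reported as `NaN` with a warning, never
#' silently as 0.
#'
#' @param t A `confusion_table` from [confusion()].
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `iou`.
#' @export
scalar_metrics <- function(t) {
  total <- t$tp + t$fp + t$tn + t$fn
  if (total <= 0) stopf("empty confusion table")
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined (0/0)", name), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  prec <- ratio(t$tp, t$tp + t$fp, "precision")
  rec <- ratio(t$tp, t$tp + t$fn, "recall")
  f1 <- ratio(2 * t$tp, 2 * t$tp + t$fp + t$fn, "f1")
  iou <- ratio(t$tp, t$tp + t$fp + t$fn, "iou")
  c(accuracy = (t$tp + t$tn) / total, precision = prec, recall = rec,
    f1 = f1, iou = iou)
}

#' ROC-AUC of per-pixel scores against a binary ground truth
#'
#' Area under the ROC curve built by sweeping all distinct score thresholds
#' with trapezoidal integration — equivalently the Mann-Whitney statistic
#' with ties counted one half. Computed over the ROI only.
#'
#' @param scores Numeric matrix of per-pixel scores for `class_id` (higher =
#'   more confident), or a [prob_map()] whose `class_id` slice is used.
#' @param truth A [label_mask()].
#' @param roi Logical matrix or `NULL` (full frame).
#' @param class_id Positive class (default 1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth, roi = NULL, class_id = 1L) {
  if (inherits(scores, "prob_map")) scores <- scores[, , class_id + 1L]
  if (!all(dim(scores) == dim(truth))) stopf("scores/truth extent mismatch")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(truth), ncol(truth))
  roi <- roi != 0
  s <- scores[roi]
  y <- truth[roi] == class_id
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stopf("ROI must contain both positive and negative pixels")
  # Mann-Whitney via midranks: ties between a positive and a negative count 1/2
  r <- rank(s, ties.method = "average")
  (sum(r[y]) - as.numeric(n_pos) * (n_pos + 1) / 2) / (as.numeric(n_pos) * n_neg)
}

#' Evaluate predictions against ground truth, per image and pooled
#'
#' Wraps [confusion()], [scalar_metrics()] and [roc_auc()] over a set of
#' images. The pooled table sums confusion counts across images before
#' computing ratios (pixel pooling); per-image averages of each metric are
#' reported alongside under `macro` for the per-image protocol.
#'
#' @param pred List of predicted [label_mask()]s (or a single mask).
#' @param truth Matching list of ground-truth masks.
#' @param scores Optional matching list of score rasters (or `prob_map`s)
#'   for AUC; `NULL` skips AUC.
#' @param roi Optional matching list of logical ROI masks, or `NULL`.
#' @param class_id Class evaluated one-vs-rest (default 1).
#' @return A `metric_report`: list with `per_image` (data.frame of counts
#'   and metrics), `pooled` (named vector), `macro` (named vector of
#'   per-image means) and `protocol`.
#' @export
evaluate_pair <- function(pred, truth, scores = NULL, roi = NULL,
                          class_id = 1L) {
  as_list <- function(x) if (is.null(x) || is.list(x)) x else list(x)
  pred <- as_list(pred); truth <- as_list(truth)
  scores <- as_list(scores); roi <- as_list(roi)
  n <- length(pred)
  if (length(truth) != n) stopf("pred and truth counts differ")
  ncs <- unique(c(vapply(pred, n_classes, integer(1L)),
                  vapply(truth, n_classes, integer(1L))))
  if (length(ncs) != 1L) stopf("inconsistent class counts across images")
  rows <- vector("list", n)
  pooled <- list(class_id = as.integer(class_id), tp = 0L, fp = 0L,
                 tn = 0L, fn = 0L)
  for (i in seq_len(n)) {
    ct <- confusion(pred[[i]], truth[[i]], roi[[i]], class_id)
    m <- suppressWarnings(scalar_metrics(ct))
    auc <- if (!is.null(scores))
      roc_auc(scores[[i]], truth[[i]], roi[[i]], class_id) else NA_real_
    rows[[i]] <- data.frame(image = i, tp = ct$tp, fp = ct$fp, tn = ct$tn,
                            fn = ct$fn, t(m), auc = auc)
    for (f in c("tp", "fp", "tn", "fn")) pooled[[f]] <- pooled[[f]] + ct[[f]]
  }
  per_image <- do.call(rbind, rows)
  class(pooled) <- "confusion_table"
  pooled_metrics <- suppressWarnings(scalar_metrics(pooled))
  if (!is.null(scores)) {
    all_s <- unlist(lapply(seq_len(n), function(i) {
      s <- scores[[i]]
      if (inherits(s, "prob_map")) s <- s[, , class_id + 1L]
      r <- if (is.null(roi[[i]])) rep(TRUE, length(s)) else roi[[i]] != 0
      s[r]
    }))
    all_y <- unlist(lapply(seq_len(n), function(i) {
      r <- if (is.null(roi[[i]])) rep(TRUE, length(truth[[i]]))
           else roi[[i]] != 0
      truth[[i]][r] == class_id
    }))
    rk <- rank(all_s, ties.method = "average")
    np <- sum(all_y); nn <- sum(!all_y)
    pooled_metrics <- c(pooled_metrics,
                        auc = (sum(rk[all_y]) - as.numeric(np) * (np + 1) / 2) / (as.numeric(np) * nn))
  }
  macro <- colMeans(per_image[, c("accuracy", "precision", "recall", "f1",
                                  "iou", "auc")], na.rm = TRUE)
  structure(list(per_image = per_image, pooled = pooled_metrics,
                 pooled_counts = pooled, macro = macro,
                 protocol = list(pooling = "pixel", class_id = class_id,
                                 roi = if (is.null(roi)) "full_frame"
                                       else "explicit")),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d image(s), class %d, %s-pooled\n",
              nrow(x$per_image), x$protocol$class_id, x$protocol$pooling))
  print(round(x$pooled, 4))
  invisible(x)
}
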