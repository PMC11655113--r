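# S3 containers shared by every module. Conventions (package-wide):
#  * rasters are stored as R matrices/arrays indexed [row, col(, channel)];
#  * the *coordinate* system is 0-based and continuous: pixel (r, c) covers
#    the square [c, c+1) x [r, r+1) and has center (c + 0.5, r + 0.5) in
#    (x, y) = (col, row) coordinates;
#  * ROIs are half-open 0-based pixel index ranges.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Label mask
#'
#' An integer class raster: one class id per pixel, `0` = non-occlusion
#' background, ids `>= 1` = occlusion classes. This container holds both
#' ground-truth masks rasterized from polygon annotations and fused
#' predictions.
#'
#' @param labels Integer matrix (rows x cols) of class ids in `[0, n_classes)`.
#' @param n_classes Number of classes, `>= 2` (binary occlusion is 2).
#' @return A `label_mask`: an integer matrix with attribute `n_classes`.
#' @export
label_mask <- function(labels, n_classes = 2L) {
  if (!is.matrix(labels)) stopf("`labels` must be a matrix")
  n_classes <- as.integer(n_classes)
  if (is.na(n_classes) || n_classes < 2L) stopf("`n_classes` must be >= 2")
  if (nrow(labels) < 1L || ncol(labels) < 1L) stopf("mask must be at least 1x1")
  storage.mode(labels) <- "integer"
  if (anyNA(labels)) stopf("labels contain NA")
  if (min(labels) < 0L || max(labels) >= n_classes)
    stopf("labels must lie in [0, %d)", n_classes)
  structure(labels, n_classes = n_classes, class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d, %d classes; occlusion pixels: %d\n",
              nrow(x), ncol(x), n_classes(x), sum(x > 0L)))
  invisible(x)
}

#' Number of classes of a raster container
#' @param x A `label_mask` or `prob_map`.
#' @return Integer class count.
#' @export
n_classes <- function(x) {
  if (inherits(x, "prob_map")) return(dim(x)[3L])
  nc <- attr(x, "n_classes")
  if (is.null(nc)) stopf("object has no class count")
  nc
}

#' Per-pixel class-probability map
#'
#' The semantic segmenter's output: for every pixel a probability
#' distribution over the `N` classes (class 0 first). Rows must sum to 1.
#'
#' @param probs Numeric array `H x W x N`, `N >= 2`, entries in `[0, 1]`,
#'   summing to 1 over the class dimension within `1e-6`.
#' @return A `prob_map` (the validated array).
#' @export
prob_map <- function(probs) {
  if (!is.array(probs) || length(dim(probs)) != 3L)
    stopf("`probs` must be an H x W x N array")
  if (dim(probs)[3L] < 2L) stopf("need at least 2 classes")
  if (anyNA(probs)) stopf("probabilities contain NA")
  if (min(probs) < 0) stopf("probabilities must be non-negative")
  sums <- rowSums(probs, dims = 2L)
  if (max(abs(sums - 1)) > 1e-6)
    stopf("per-pixel probabilities must sum to 1 (max deviation %.3g)",
          max(abs(sums - 1)))
  structure(probs, class = "prob_map")
}

#' @export
print.prob_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<prob_map> %d x %d, %d classes\n", d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Per-pixel argmax of a probability map
#'
#' Ties break to the lowest class id, matching the fusion's vote tie rule.
#'
#' @param probs A `prob_map`.
#' @return A `label_mask` of the same extent.
#' @export
prob_argmax <- function(probs) {
  d <- dim(probs)
  flat <- matrix(probs, d[1L] * d[2L], d[3L])
  win <- max.col(flat, ties.method = "first") - 1L
  label_mask(matrix(as.integer(win), d[1L], d[2L]), n_classes = d[3L])
}

#' Segment stack
#'
#' The automatic-mask-generator output shape: an ordered set of binary
#' segment masks over one frame, each with the generator's predicted
#' confidence (IoU prediction) and stability score. Masks may overlap.
#'
#' @param masks List of logical matrices, all of one common extent, each with
#'   at least one set pixel.
#' @param predicted_confidence,stability Numeric vectors in `[0, 1]`, one
#'   value per mask.
#' @param height,width Frame extent; required only when `masks` is empty.
#' @return A `segment_stack`: list with `height`, `width` and `segments`, the
#'   latter an ordered list of records `mask`/`predicted_confidence`/
#'   `stability`/`area`.
#' @export
segment_stack <- function(masks, predicted_confidence = NULL, stability = NULL,
                          height = NULL, width = NULL) {
  n <- length(masks)
  if (is.null(predicted_confidence)) predicted_confidence <- rep(1, n)
  if (is.null(stability)) stability <- rep(1, n)
  if (length(predicted_confidence) != n || length(stability) != n)
    stopf("need one confidence and one stability per mask")
  if (n == 0L) {
    if (is.null(height) || is.null(width))
      stopf("empty stack needs explicit height/width")
  } else {
    height <- nrow(masks[[1L]]); width <- ncol(masks[[1L]])
  }
  if (height < 1L || width < 1L) stopf("invalid frame extent")
  bad <- c(predicted_confidence, stability)
  if (anyNA(bad) || min(bad, 1) < 0 || max(bad, 0) > 1)
    stopf("confidence and stability must lie in [0, 1]")
  segments <- vector("list", n)
  for (i in seq_len(n)) {
    m <- masks[[i]]
    if (!is.matrix(m)) stopf("segment %d: mask must be a matrix", i)
    m <- m != 0
    if (anyNA(m)) stopf("segment %d: mask contains NA", i)
    if (nrow(m) != height || ncol(m) != width)
      stopf("segment %d: extent %dx%d differs from stack %dx%d",
            i, nrow(m), ncol(m), height, width)
    a <- sum(m)
    if (a < 1L) stopf("segment %d: empty mask", i)
    segments[[i]] <- list(mask = m,
                          predicted_confidence = predicted_confidence[[i]],
                          stability = stability[[i]],
                          area = as.integer(a))
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 segments = segments),
            class = "segment_stack")
}

#' @export
print.segment_stack <- function(x, ...) {
  cat(sprintf("<segment_stack> %d x %d, %d segments\n",
              x$height, x$width, length(x$segments)))
  invisible(x)
}

#' @export
length.segment_stack <- function(x) length(x$segments)

segment_areas <- function(stack) {
  vapply(stack$segments, `[[`, integer(1L), "area")
}

#' Polygon annotation
#'
#' One labeled polygon in continuous image coordinates. Polygons annotate
#' occlusions only, so `class_id >= 1`.
#'
#' @param vertices Numeric `n x 2` matrix of `(x, y)` vertices, `n >= 3`.
#' @param class_id Occlusion class id, integer `>= 1`.
#' @param image_id Optional source-image identifier.
#' @return A `polygon_annotation`.
#' @export
polygon_annotation <- function(vertices, class_id = 1L, image_id = "") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L) stopf("vertices must be an n x 2 (x, y) matrix")
  if (nrow(vertices) < 3L)
    stopf("polygon needs at least 3 vertices, got %d", nrow(vertices))
  if (!all(is.finite(vertices))) stopf("vertices must be finite")
  class_id <- as.integer(class_id)
  if (is.na(class_id) || class_id < 1L)
    stopf("class_id must be an integer >= 1")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, class_id = class_id,
                 image_id = as.character(image_id)),
            class = "polygon_annotation")
}

#' Rectangular region of interest
#'
#' Half-open, 0-based pixel index ranges: rows `[row_start, row_end)`,
#' columns `[col_start, col_end)`.
#'
#' @param row_start,row_end,col_start,col_end Pixel indices.
#' @return A `roi`.
#' @export
roi <- function(row_start, row_end, col_start, col_end) {
  v <- as.integer(c(row_start, row_end, col_start, col_end))
  if (anyNA(v)) stopf("roi bounds must be integers")
  if (v[1L] < 0L || v[1L] >= v[2L] || v[3L] < 0L || v[3L] >= v[4L])
    stopf("roi must satisfy 0 <= start < end on both axes")
  structure(list(row_start = v[1L], row_end = v[2L],
                 col_start = v[3L], col_end = v[4L]),
            class = "roi")
}

roi_check <- function(roi, height, width) {
  if (roi$row_end > height || roi$col_end > width)
    stopf("roi [%d,%d)x[%d,%d) exceeds raster extent %dx%d",
          roi$row_start, roi$row_end, roi$col_start, roi$col_end,
          height, width)
  invisible(roi)
}

# 1-based R index ranges of a 0-based half-open roi
roi_rows <- function(roi) (roi$row_start + 1L):roi$row_end
roi_cols <- function(roi) (roi$col_start + 1L):roi$col_end

#' One-hot probability map from a label mask
#'
#' @param mask A `label_mask`.
#' @param n_classes Class count; defaults to the mask's.
#' @return A `prob_map` with probability 1 on each pixel's class.
#' @export
one_hot <- function(mask, n_classes = NULL) {
  if (is.null(n_classes)) n_classes <- n_classes(mask)
  h <- nrow(mask); w <- ncol(mask)
  probs <- array(0, c(h, w, n_classes))
  idx <- cbind(rep(seq_len(h), w), rep(seq_len(w), each = h),
               as.vector(mask) + 1L)
  probs[idx] <- 1
  prob_map(probs)
}

#' Display a label mask
#'
#' @param x A `label_mask`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.label_mask <- function(x, ...) {
  nc <- n_classes(x)
  graphics::image(t(x)[, nrow(x):1, drop = FALSE], zlim = c(0, nc - 1L),
                  col = grDevices::hcl.colors(nc, "viridis"),
                  axes = FALSE, asp = nrow(x) / ncol(x), ...)
  invisible(x)
}
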