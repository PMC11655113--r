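# Confidence-based soft-voting fusion: assign one semantic class to every
# class-agnostic segment proposal by summing the semantic per-pixel class
# probabilities over the segment and taking the argmax, then composite the
# winners into a label mask. Under the working assumption that proposals
# never straddle object boundaries (any two pixels of one segment share a
# hidden occlusion class), the proposals are the finest granularity the
# fused output needs.

#' Fusion configuration
#'
#' Quality filters and composition policies for [soss_fuse()]. The default
#' thresholds keep segments with predicted confidence of at least 90%,
#' stability of at least 85% and area of at least 5 pixels; all thresholds
#' are inclusive.
#'
#' @param min_confidence,min_stability Minimum generator scores in `[0, 1]`.
#' @param min_area Minimum segment area in pixels (`>= 1`).
#' @param uncovered_policy Class for pixels no surviving segment covers:
#'   `"background"` (class 0) or `"semantic_argmax"` (per-pixel argmax of the
#'   probability map).
#' @param overlap_policy Overlap resolution: `"smaller_wins"` applies
#'   segments in decreasing area order so finer-detail segments overwrite
#'   coarser ones; `"larger_wins"` the reverse.
#' @return A `fusion_config`.
#' @export
fusion_config <- function(min_confidence = 0.90, min_stability = 0.85,
                          min_area = 5L,
                          uncovered_policy = c("background", "semantic_argmax"),
                          overlap_policy = c("smaller_wins", "larger_wins")) {
  if (min_confidence < 0 || min_confidence > 1 ||
      min_stability < 0 || min_stability > 1)
    stopf("score thresholds must lie in [0, 1]")
  min_area <- as.integer(min_area)
  if (is.na(min_area) || min_area < 1L) stopf("min_area must be >= 1")
  structure(list(min_confidence = min_confidence,
                 min_stability = min_stability,
                 min_area = min_area,
                 uncovered_policy = match.arg(uncovered_policy),
                 overlap_policy = match.arg(overlap_policy),
                 tie_policy = "lowest_class"),
            class = "fusion_config")
}

#' Regular point grid for prompting an automatic mask generator
#'
#' Places `n_per_side^2` prompt points at cell centers: along each axis,
#' point `i` (0-based) sits at `(i + 0.5) / n_per_side` of the extent, so
#' every point is strictly inside the image. A 40 x 40 grid gives the point
#' density needed for small occlusions such as electrodes and thin cables.
#'
#' @param height,width Image extent in pixels.
#' @param n_per_side Points per axis (default 40).
#' @return Numeric `n_per_side^2 x 2` matrix of `(x, y)` points, row-major
#'   over the grid (x fastest).
#' @export
grid_prompt_points <- function(height, width, n_per_side = 40L) {
  height <- as.numeric(height); width <- as.numeric(width)
  if (is.na(height) || is.na(width) || height <= 0 || width <= 0)
    stopf("image extent must be positive")
  n <- as.integer(n_per_side)
  if (is.na(n) || n < 1L) stopf("n_per_side must be >= 1")
  frac <- (seq_len(n) - 0.5) / n
  pts <- cbind(x = rep(frac * width, times = n),
               y = rep(frac * height, each = n))
  pts
}

#' Filter a segment stack on generator quality scores and area
#'
#' Keeps exactly the segments with `predicted_confidence >= min_confidence`,
#' `stability >= min_stability` and `area >= min_area` (all inclusive),
#' preserving order. Dropping every segment is legal.
#'
#' @param stack A [segment_stack()].
#' @param config A [fusion_config()].
#' @return The filtered [segment_stack()].
#' @export
filter_segments <- function(stack, config = fusion_config()) {
  keep <- vapply(stack$segments, function(s) {
    s$predicted_confidence >= config$min_confidence &&
      s$stability >= config$min_stability &&
      s$area >= config$min_area
  }, logical(1L))
  structure(list(height = stack$height, width = stack$width,
                 segments = stack$segments[keep]),
            class = "segment_stack")
}

#' Soft vote of one segment over a probability map
#'
#' Masks the probability map with the segment and sums per class over the
#' segment's pixels; the winning class is the argmax of the summed
#' confidences, ties broken to the lowest class id (so an exact tie defaults
#' to non-occlusion). Summing probabilities rather than counting hard labels
#' bounds every pixel's influence at 1, tempering segmenter overconfidence.
#'
#' @param probs A [prob_map()].
#' @param segment_mask Logical matrix of the segment, same extent.
#' @return List with `votes` (length-N numeric) and `winner` (class id).
#' @export
segment_vote <- function(probs, segment_mask) {
  d <- dim(probs)
  if (nrow(segment_mask) != d[1L] || ncol(segment_mask) != d[2L])
    stopf("segment extent %dx%d differs from map %dx%d",
          nrow(segment_mask), ncol(segment_mask), d[1L], d[2L])
  segment_mask <- segment_mask != 0
  if (!any(segment_mask)) stopf("empty segment")
  flat <- matrix(probs, d[1L] * d[2L], d[3L])
  votes <- colSums(flat[as.vector(segment_mask), , drop = FALSE])
  list(votes = votes, winner = which.max(votes) - 1L)
}

# Application order of segments under an overlap policy: later application
# overwrites earlier. Ties in area keep stack order (later segment wins).
segment_order <- function(stack, overlap_policy) {
  areas <- segment_areas(stack)
  if (length(areas) == 0L) return(integer(0L))
  decreasing <- overlap_policy == "smaller_wins"
  order(areas, decreasing = decreasing)
}

#' Fuse a semantic probability map with a segment stack
#'
#' The soft-voting fusion: every surviving segment (after
#' [filter_segments()]) gets the class voted by [segment_vote()], and its
#' pixels take that class in the output. Overlaps resolve by
#' `config$overlap_policy`; pixels covered by no surviving segment get class
#' 0 (`uncovered_policy = "background"`) or the per-pixel semantic argmax
#' (`"semantic_argmax"`). Within any surviving segment's non-overlapped
#' pixels the output class is constant.
#'
#' @param probs A [prob_map()].
#' @param stack A [segment_stack()] on the same extent.
#' @param config A [fusion_config()].
#' @param filter Apply [filter_segments()] first (default); set `FALSE` when
#'   the stack is pre-filtered.
#' @return A [label_mask()].
#' @export
soss_fuse <- function(probs, stack, config = fusion_config(), filter = TRUE) {
  d <- dim(probs)
  if (stack$height != d[1L] || stack$width != d[2L])
    stopf("stack extent %dx%d differs from map %dx%d",
          stack$height, stack$width, d[1L], d[2L])
  if (filter) stack <- filter_segments(stack, config)
  out <- if (config$uncovered_policy == "semantic_argmax")
    matrix(as.integer(prob_argmax(probs)), d[1L], d[2L])
  else matrix(0L, d[1L], d[2L])
  for (i in segment_order(stack, config$overlap_policy)) {
    s <- stack$segments[[i]]
    out[s$mask] <- segment_vote(probs, s$mask)$winner
  }
  label_mask(out, d[3L])
}

#' Per-pixel soft scores of the fused segmentation
#'
#' Companion to [soss_fuse()] for threshold-sweep evaluation (ROC/AUC): each
#' covered pixel carries its segment's vote vector normalized by the segment
#' area (a probability distribution, since per-pixel probabilities are
#' bounded by 1), with overlaps resolved exactly as in [soss_fuse()].
#' Uncovered pixels keep the original probabilities under
#' `"semantic_argmax"`, or the one-hot of class 0 under `"background"`.
#' The argmax of the result equals the [soss_fuse()] output everywhere.
#'
#' @inheritParams soss_fuse
#' @return A [prob_map()].
#' @export
fused_soft_scores <- function(probs, stack, config = fusion_config(),
                              filter = TRUE) {
  d <- dim(probs)
  if (stack$height != d[1L] || stack$width != d[2L])
    stopf("stack extent %dx%d differs from map %dx%d",
          stack$height, stack$width, d[1L], d[2L])
  if (filter) stack <- filter_segments(stack, config)
  if (config$uncovered_policy == "semantic_argmax") {
    scores <- array(unclass(probs), d)
  } else {
    scores <- array(0, d)
    scores[, , 1L] <- 1
  }
  flat <- matrix(scores, d[1L] * d[2L], d[3L])
  for (i in segment_order(stack, config$overlap_policy)) {
    s <- stack$segments[[i]]
    v <- segment_vote(probs, s$mask)
    flat[as.vector(s$mask), ] <- rep(v$votes / s$area, each = s$area)
  }
  prob_map(array(flat, d))
}
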