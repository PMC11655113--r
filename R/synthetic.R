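# Seeded synthetic scenes with exact ground truth, plus controlled
# degradations that emulate the statistical structure of the two model
# outputs the fusion consumes: a semantic probability map with blurred
# boundaries and per-pixel label noise (the coarse segmenter), and an
# over-segmented partition whose pieces respect ground-truth object
# boundaries (the class-agnostic proposal generator). This makes the
# fusion's improvement claim testable with no image data.

# Evaluate `code` under a temporary RNG state so generators are pure
# functions of their seed.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

disc_brush <- function(r) EBImage::makeBrush(2L * as.integer(r) + 1L, "disc")

binary_dilate <- function(mask, r) {
  if (r < 1L) return(mask)
  EBImage::dilate(mask * 1, disc_brush(r)) > 0.5
}

binary_erode <- function(mask, r) {
  if (r < 1L) return(mask)
  EBImage::erode(mask * 1, disc_brush(r)) > 0.5
}

#' Synthetic scene configuration
#'
#' Scenes emulate the object repertoire of bedside occlusion imagery:
#' compact blobs (pillows, patches), elongated bars (rails, boards) and thin
#' meandering cables — objects of various kinds, shapes and sizes on a
#' background.
#'
#' @param height,width Frame extent (default 128).
#' @param n_objects_range Inclusive range for the object count.
#' @param object_kinds Subset of `"blob"`, `"bar"`, `"cable"`.
#' @param cable_thickness_range Inclusive dilation-radius range for cables;
#'   1 gives cables a few pixels wide.
#' @param n_classes Class count (default 2: background + occlusion).
#' @param seed Scene RNG seed.
#' @return A `scene_spec`.
#' @export
scene_spec <- function(height = 128L, width = 128L,
                       n_objects_range = c(3L, 6L),
                       object_kinds = c("blob", "bar", "cable"),
                       cable_thickness_range = c(1L, 2L),
                       n_classes = 2L, seed = 1L) {
  object_kinds <- match.arg(object_kinds, several.ok = TRUE)
  if (height < 16L || width < 16L) stopf("frame must be at least 16x16")
  if (n_objects_range[1L] > n_objects_range[2L] || n_objects_range[1L] < 0L)
    stopf("n_objects_range must be an ordered non-negative pair")
  if (cable_thickness_range[1L] < 1L ||
      cable_thickness_range[1L] > cable_thickness_range[2L])
    stopf("cable_thickness_range must be ordered with minimum >= 1")
  if (2L * cable_thickness_range[2L] + 1L > min(height, width))
    stopf("cable thickness exceeds the frame")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_objects_range = as.integer(n_objects_range),
                 object_kinds = object_kinds,
                 cable_thickness_range = as.integer(cable_thickness_range),
                 n_classes = as.integer(n_classes), seed = as.integer(seed)),
            class = "scene_spec")
}

#' Degradation configuration
#'
#' Controls how far the synthetic probability map and segment stack depart
#' from the ground truth. The probability-map model is i.i.d. label flips on
#' top of per-object boundary jitter — the weakest noise under which
#' per-segment majority voting provably helps. Segment confidence/stability
#' are drawn above the default fusion filters; `weak_scores = TRUE` draws
#' them from `[0, 1]` instead to exercise the filters, and `impure_rate`
#' injects boundary-crossing segments to stress the class-purity assumption.
#'
#' @param boundary_jitter_radius Max per-object dilation/erosion radius, px.
#' @param label_flip_rate Per-pixel probability of flipping to a uniformly
#'   random other class.
#' @param confidence_temperature Softening temperature `T > 0`: the winning
#'   class gets weight `1 / (1 + (N-1) exp(-1/T))`; `T -> 0` recovers the
#'   one-hot limit.
#' @param segment_split_mean Each ground-truth region is split into
#'   `1 + Poisson(segment_split_mean)` pieces.
#' @param segment_drop_rate Probability that a small occlusion object
#'   (area `<=` `min_dropped_object_area`) is omitted from the stack
#'   entirely, emulating proposals missing thin objects.
#' @param min_dropped_object_area Area threshold for dropping.
#' @param weak_scores,impure_rate Stress flags (see above).
#' @param seed Degradation RNG seed.
#' @return A `degrade_spec`.
#' @export
degrade_spec <- function(boundary_jitter_radius = 2L, label_flip_rate = 0.15,
                         confidence_temperature = 0.25,
                         segment_split_mean = 2, segment_drop_rate = 0,
                         min_dropped_object_area = 30L,
                         weak_scores = FALSE, impure_rate = 0,
                         seed = 1L) {
  rates <- c(label_flip_rate, segment_drop_rate, impure_rate)
  if (anyNA(rates) || min(rates) < 0 || max(rates) > 1)
    stopf("rates must lie in [0, 1]")
  if (confidence_temperature <= 0) stopf("temperature must be positive")
  if (segment_split_mean < 0) stopf("segment_split_mean must be >= 0")
  structure(list(boundary_jitter_radius = as.integer(boundary_jitter_radius),
                 label_flip_rate = label_flip_rate,
                 confidence_temperature = confidence_temperature,
                 segment_split_mean = segment_split_mean,
                 segment_drop_rate = segment_drop_rate,
                 min_dropped_object_area = as.integer(min_dropped_object_area),
                 weak_scores = isTRUE(weak_scores),
                 impure_rate = impure_rate,
                 seed = as.integer(seed)),
            class = "degrade_spec")
}

draw_blob <- function(h, w) {
  cy <- stats::runif(1, 0.15 * h, 0.85 * h)
  cx <- stats::runif(1, 0.15 * w, 0.85 * w)
  a <- stats::runif(1, 0.05, 0.18) * min(h, w)
  b <- stats::runif(1, 0.05, 0.18) * min(h, w)
  th <- stats::runif(1, 0, pi)
  r <- rep(seq_len(h) - 0.5, w); c <- rep(seq_len(w) - 0.5, each = h)
  u <- (c - cx) * cos(th) + (r - cy) * sin(th)
  v <- -(c - cx) * sin(th) + (r - cy) * cos(th)
  matrix((u / a)^2 + (v / b)^2 <= 1, h, w)
}

draw_bar <- function(h, w) {
  cy <- stats::runif(1, 0.15 * h, 0.85 * h)
  cx <- stats::runif(1, 0.15 * w, 0.85 * w)
  len <- stats::runif(1, 0.25, 0.6) * min(h, w)
  wid <- stats::runif(1, 2, 6)
  th <- stats::runif(1, 0, pi)
  r <- rep(seq_len(h) - 0.5, w); c <- rep(seq_len(w) - 0.5, each = h)
  u <- (c - cx) * cos(th) + (r - cy) * sin(th)
  v <- -(c - cx) * sin(th) + (r - cy) * cos(th)
  matrix(abs(u) <= len / 2 & abs(v) <= wid / 2, h, w)
}

draw_cable <- function(h, w, thickness) {
  n_steps <- as.integer(stats::runif(1, 0.8, 1.6) * min(h, w))
  r <- stats::runif(1, 0.2 * h, 0.8 * h)
  c <- stats::runif(1, 0.2 * w, 0.8 * w)
  th <- stats::runif(1, 0, 2 * pi)
  path <- matrix(FALSE, h, w)
  for (i in seq_len(n_steps)) {
    th <- th + stats::rnorm(1, 0, 0.25)
    r <- min(max(r + sin(th), 1), h)
    c <- min(max(c + cos(th), 1), w)
    path[round(r), round(c)] <- TRUE
  }
  binary_dilate(path, thickness)
}

#' Generate a synthetic scene with ground truth
#'
#' Draws a seeded number of occlusion objects onto a background (later
#' objects overwrite earlier where they overlap) and renders an RGB image
#' in which every object gets a distinct mean color plus white noise.
#' Bit-identical output for identical specs.
#'
#' @param spec A [scene_spec()].
#' @return List with `truth` (a [label_mask()]) and `image`
#'   (`H x W x 3`, values in `[0, 255]`).
#' @export
make_scene <- function(spec = scene_spec()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    n_obj <- if (spec$n_objects_range[1L] == spec$n_objects_range[2L])
      spec$n_objects_range[1L]
    else sample(spec$n_objects_range[1L]:spec$n_objects_range[2L], 1L)
    labels <- matrix(0L, h, w)
    image <- array(0, c(h, w, 3L))
    bg <- stats::runif(3, 40, 90)
    for (ch in 1:3) image[, , ch] <- bg[ch]
    for (k in seq_len(n_obj)) {
      kind <- if (length(spec$object_kinds) == 1L) spec$object_kinds
              else sample(spec$object_kinds, 1L)
      m <- switch(kind,
        blob = draw_blob(h, w),
        bar = draw_bar(h, w),
        cable = {
          tr <- spec$cable_thickness_range
          t <- if (tr[1L] == tr[2L]) tr[1L] else sample(tr[1L]:tr[2L], 1L)
          draw_cable(h, w, t)
        })
      if (!any(m)) next
      cls <- if (spec$n_classes == 2L) 1L
             else sample(seq_len(spec$n_classes - 1L), 1L)
      labels[m] <- cls
      col <- stats::runif(3, 100, 250)
      for (ch in 1:3) image[, , ch][m] <- col[ch]
    }
    image <- image + array(stats::rnorm(h * w * 3L, 0, 8), c(h, w, 3L))
    list(truth = label_mask(labels, spec$n_classes),
         image = pmin(pmax(image, 0), 255))
  })
}

#' Degrade a ground-truth mask into a noisy probability map
#'
#' Emulates a coarse semantic segmenter: each occlusion object's boundary is
#' displaced by a random-radius dilation or erosion (up to
#' `boundary_jitter_radius`), per-pixel labels flip to a random other class
#' with `label_flip_rate`, and the resulting hard labels become
#' probabilities by temperature-softened one-hot encoding (rows sum to 1).
#'
#' @param truth A [label_mask()].
#' @param spec A [degrade_spec()].
#' @return A [prob_map()] with the same extent and class count.
#' @export
degrade_to_probmap <- function(truth, spec = degrade_spec()) {
  stopifnot(inherits(truth, "label_mask"), inherits(spec, "degrade_spec"))
  nc <- n_classes(truth)
  with_seed(spec$seed, {
    working <- matrix(as.integer(unclass(truth)), nrow(truth), ncol(truth))
    if (spec$boundary_jitter_radius > 0L) {
      for (cls in seq_len(nc - 1L)) {
        comp <- EBImage::bwlabel((unclass(truth) == cls) * 1)
        for (id in setdiff(sort(unique(as.vector(comp))), 0)) {
          m <- comp == id
          r <- sample(0:spec$boundary_jitter_radius, 1L)
          if (r == 0L) next
          if (stats::runif(1) < 0.5) {
            working[binary_dilate(m, r) & working == 0L] <- cls
          } else {
            working[m & !binary_erode(m, r)] <- 0L
          }
        }
      }
    }
    if (spec$label_flip_rate > 0) {
      flip <- stats::runif(length(working)) < spec$label_flip_rate
      shift <- sample.int(nc - 1L, sum(flip), replace = TRUE)
      working[flip] <- (working[flip] + shift) %% nc
    }
    # temperature-softened one-hot, numerically stable for small T
    e <- exp(-1 / spec$confidence_temperature)
    p_win <- 1 / (1 + (nc - 1) * e)
    p_other <- (1 - p_win) / (nc - 1)
    probs <- array(p_other, c(nrow(working), ncol(working), nc))
    idx <- cbind(rep(seq_len(nrow(working)), ncol(working)),
                 rep(seq_len(ncol(working)), each = nrow(working)),
                 as.vector(working) + 1L)
    probs[idx] <- p_win
    prob_map(probs)
  })
}

# nearest-seed partition of one region's pixels; ties to the lowest seed
split_region <- function(px, n_pieces) {
  n_pieces <- min(n_pieces, nrow(px))
  if (n_pieces <= 1L) return(rep(1L, nrow(px)))
  seeds <- px[sample.int(nrow(px), n_pieces), , drop = FALSE]
  d2 <- outer(px[, 1L], seeds[, 1L], "-")^2 + outer(px[, 2L], seeds[, 2L], "-")^2
  max.col(-d2, ties.method = "first")
}

#' Shatter a ground-truth mask into class-pure segment proposals
#'
#' Emulates an automatic mask generator: every 4-connected region of the
#' truth (background included — the generator partitions the whole frame)
#' is split into `1 + Poisson(segment_split_mean)` pieces by nearest-seed
#' assignment of random in-region seeds, so no segment crosses a truth
#' boundary and the same-segment-same-class assumption holds by
#' construction. Small occlusion objects can be dropped entirely (see
#' [degrade_spec()]); surviving segments get confidence in `[0.92, 1]` and
#' stability in `[0.88, 1]`, above the default fusion filters.
#'
#' @param truth A [label_mask()].
#' @param spec A [degrade_spec()].
#' @return A [segment_stack()].
#' @export
shatter_to_segments <- function(truth, spec = degrade_spec()) {
  stopifnot(inherits(truth, "label_mask"), inherits(spec, "degrade_spec"))
  nc <- n_classes(truth)
  with_seed(spec$seed + 1L, {
    masks <- list()
    h <- nrow(truth); w <- ncol(truth)
    for (cls in 0:(nc - 1L)) {
      cm <- (unclass(truth) == cls) * 1
      if (!any(cm > 0)) next
      comp <- EBImage::bwlabel(cm)
      for (id in setdiff(sort(unique(as.vector(comp))), 0)) {
        px <- which(comp == id, arr.ind = TRUE)
        if (cls >= 1L && nrow(px) <= spec$min_dropped_object_area &&
            stats::runif(1) < spec$segment_drop_rate) next
        pieces <- 1L + stats::rpois(1L, spec$segment_split_mean)
        assign <- split_region(px, pieces)
        for (p in sort(unique(assign))) {
          m <- matrix(FALSE, h, w)
          m[px[assign == p, , drop = FALSE]] <- TRUE
          if (spec$impure_rate > 0 && stats::runif(1) < spec$impure_rate)
            m <- binary_dilate(m, 1L)    # stress: may cross truth boundaries
          masks[[length(masks) + 1L]] <- m
        }
      }
    }
    n <- length(masks)
    if (spec$weak_scores) {
      conf <- stats::runif(n); stab <- stats::runif(n)
    } else {
      conf <- stats::runif(n, 0.92, 1); stab <- stats::runif(n, 0.88, 1)
    }
    segment_stack(masks, conf, stab, height = h, width = w)
  })
}

#' Semantic-only vs fused IoU over seeded synthetic scenes
#'
#' For each seed: generate a scene, degrade it to a probability map and a
#' class-pure segment stack, then compare the occlusion-class IoU of the
#' per-pixel semantic argmax against the soft-voting fusion (uncovered
#' pixels fall back to the semantic argmax). Majority voting over class-pure
#' segments removes isolated label flips, so under majority-correct noise
#' the fused IoU should dominate.
#'
#' @param scene A [scene_spec()]; its `seed` is the base seed.
#' @param degrade A [degrade_spec()]; reseeded per scene.
#' @param n_seeds Number of scenes.
#' @param config A [fusion_config()]; the default uses the
#'   `semantic_argmax` uncovered policy.
#' @param class_id Occlusion class evaluated (default 1).
#' @return Data frame with columns `seed`, `iou_semantic`, `iou_fused`.
#' @export
improvement_experiment <- function(scene = scene_spec(),
                                   degrade = degrade_spec(),
                                   n_seeds = 20L,
                                   config = fusion_config(
                                     uncovered_policy = "semantic_argmax"),
                                   class_id = 1L) {
  n_seeds <- as.integer(n_seeds)
  if (n_seeds < 1L) stopf("n_seeds must be >= 1")
  iou_of <- function(pred, truth)
    unname(suppressWarnings(
      scalar_metrics(confusion(pred, truth, class_id = class_id))["iou"]))
  rows <- lapply(seq_len(n_seeds) - 1L, function(k) {
    sc <- scene; sc$seed <- scene$seed + k
    dg <- degrade; dg$seed <- degrade$seed + 7919L * k
    truth <- make_scene(sc)$truth
    probs <- degrade_to_probmap(truth, dg)
    stack <- shatter_to_segments(truth, dg)
    pred_sem <- prob_argmax(probs)
    pred_fused <- soss_fuse(probs, stack, config)
    data.frame(seed = sc$seed,
               iou_semantic = iou_of(pred_sem, truth),
               iou_fused = iou_of(pred_fused, truth))
  })
  do.call(rbind, rows)
}
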