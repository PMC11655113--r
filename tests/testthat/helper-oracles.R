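# Independent brute-force oracles: plain loops, no vectorization, no reuse
# of package internals. Used to pin down the fusion, rasterization and AUC
# semantics on small random instances.

# per-pixel argmax by explicit loops, ties to the lowest class
oracle_argmax <- function(probs) {
  d <- dim(probs)
  out <- matrix(0L, d[1L], d[2L])
  for (r in seq_len(d[1L])) for (c in seq_len(d[2L])) {
    best <- 1L
    for (k in seq_len(d[3L])) if (probs[r, c, k] > probs[r, c, best]) best <- k
    out[r, c] <- best - 1L
  }
  out
}

# full fusion semantics re-derived with loops: filter, order by area under
# the overlap policy, vote per segment, composite
oracle_soss <- function(probs, stack, config) {
  d <- dim(probs)
  keep <- list()
  for (s in stack$segments) {
    if (s$predicted_confidence >= config$min_confidence &&
        s$stability >= config$min_stability &&
        s$area >= config$min_area) keep[[length(keep) + 1L]] <- s
  }
  out <- if (config$uncovered_policy == "semantic_argmax") oracle_argmax(probs)
         else matrix(0L, d[1L], d[2L])
  areas <- numeric(length(keep))
  for (i in seq_along(keep)) areas[i] <- sum(keep[[i]]$mask)
  ord <- order(areas, decreasing = config$overlap_policy == "smaller_wins")
  for (i in ord) {
    m <- keep[[i]]$mask
    votes <- numeric(d[3L])
    for (r in seq_len(d[1L])) for (c in seq_len(d[2L])) {
      if (m[r, c]) for (k in seq_len(d[3L]))
        votes[k] <- votes[k] + probs[r, c, k]
    }
    winner <- 1L
    for (k in seq_len(d[3L])) if (votes[k] > votes[winner]) winner <- k
    for (r in seq_len(d[1L])) for (c in seq_len(d[2L]))
      if (m[r, c]) out[r, c] <- winner - 1L
  }
  out
}

# even-odd point-in-polygon, one point at a time
oracle_point_in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > y) != (vy[j] > y)) {
      x_cross <- (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (x < x_cross) inside <- !inside
    }
    j <- i
  }
  inside
}

oracle_rasterize <- function(annotations, height, width) {
  out <- matrix(0L, height, width)
  for (a in annotations) {
    for (r in seq_len(height)) for (c in seq_len(width)) {
      if (oracle_point_in_polygon(c - 0.5, r - 0.5,
                                  a$vertices[, 1L], a$vertices[, 2L]))
        out[r, c] <- a$class_id
    }
  }
  out
}

# exhaustive pairwise Mann-Whitney with ties counted one half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (n in neg) {
    if (p > n) total <- total + 1
    else if (p == n) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}

# random normalized probability map
rand_probs <- function(h, w, n_cls) {
  p <- array(stats::runif(h * w * n_cls), c(h, w, n_cls))
  prob_map(p / array(rep(rowSums(p, dims = 2L), n_cls), c(h, w, n_cls)))
}

# random (possibly overlapping) segment stack; scores span the filter
# thresholds so filtering paths get exercised
rand_stack <- function(h, w, max_segments = 6L) {
  n <- sample(0:max_segments, 1L)
  masks <- list(); conf <- numeric(0); stab <- numeric(0)
  for (i in seq_len(n)) {
    m <- matrix(stats::runif(h * w) < stats::runif(1, 0.05, 0.6), h, w)
    if (!any(m)) m[sample.int(h, 1L), sample.int(w, 1L)] <- TRUE
    masks[[length(masks) + 1L]] <- m
    conf <- c(conf, stats::runif(1, 0.7, 1))
    stab <- c(stab, stats::runif(1, 0.7, 1))
  }
  segment_stack(masks, conf, stab, height = h, width = w)
}

rand_fusion_config <- function() {
  fusion_config(
    min_confidence = sample(c(0.9, 0.75, 0), 1L),
    min_stability = sample(c(0.85, 0.8, 0), 1L),
    min_area = sample(1:5, 1L),
    uncovered_policy = sample(c("background", "semantic_argmax"), 1L),
    overlap_policy = sample(c("smaller_wins", "larger_wins"), 1L))
}

# disjoint random partition-like stack: every pixel in at most one segment
rand_disjoint_stack <- function(h, w, max_segments = 6L) {
  groups <- matrix(sample.int(max_segments + 1L, h * w, replace = TRUE), h, w)
  masks <- list()
  for (g in seq_len(max_segments)) {
    m <- groups == g
    if (any(m)) masks[[length(masks) + 1L]] <- m
  }
  segment_stack(masks, height = h, width = w)
}

expect_same_labels <- function(a, b) {
  expect_identical(matrix(as.integer(a), nrow(a), ncol(a)),
                   matrix(as.integer(b), nrow(b), ncol(b)))
}
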