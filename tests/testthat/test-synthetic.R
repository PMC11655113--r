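# Synthetic scenes, controlled degradations, and the fusion-vs-semantic
# improvement experiment.

test_that("scene generation is a pure function of its spec", {
  sp <- scene_spec(height = 48L, width = 48L, seed = 9L)
  a <- make_scene(sp); b <- make_scene(sp)
  expect_identical(a$image, b$image)
  expect_same_labels(a$truth, b$truth)
  # a different seed gives a different scene
  d <- make_scene(scene_spec(height = 48L, width = 48L, seed = 10L))
  expect_false(identical(c(unclass(a$truth)), c(unclass(d$truth))))
  # generation does not disturb the session RNG stream
  set.seed(1); before <- stats::runif(3)
  set.seed(1); invisible(make_scene(sp)); after <- stats::runif(3)
  expect_identical(before, after)
})

test_that("empty and degenerate scene specs behave", {
  sp0 <- scene_spec(height = 32L, width = 32L, n_objects_range = c(0L, 0L))
  expect_true(all(make_scene(sp0)$truth == 0L))
  expect_error(scene_spec(height = 8L, width = 32L), "16x16")
  expect_error(scene_spec(cable_thickness_range = c(3L, 1L)), "ordered")
})

test_that("cables are thin but connected objects of bounded-below area", {
  sp <- scene_spec(height = 64L, width = 64L, n_objects_range = c(1L, 1L),
                   object_kinds = "cable",
                   cable_thickness_range = c(1L, 1L), seed = 4L)
  truth <- make_scene(sp)$truth
  expect_gte(sum(truth == 1L), 10L)
})

test_that("noiseless degradation recovers the truth in the argmax", {
  truth <- make_scene(scene_spec(height = 32L, width = 32L, seed = 2L))$truth
  dg <- degrade_spec(boundary_jitter_radius = 0L, label_flip_rate = 0,
                     confidence_temperature = 0.01, seed = 5L)
  pm <- degrade_to_probmap(truth, dg)
  expect_same_labels(prob_argmax(pm), truth)
  expect_true(max(abs(rowSums(unclass(pm), dims = 2L) - 1)) < 1e-9)
})

test_that("full label corruption with two classes complements the truth", {
  truth <- make_scene(scene_spec(height = 32L, width = 32L, seed = 2L))$truth
  dg <- degrade_spec(boundary_jitter_radius = 0L, label_flip_rate = 1,
                     seed = 5L)
  pm <- degrade_to_probmap(truth, dg)
  expect_same_labels(prob_argmax(pm), label_mask(1L - unclass(truth), 2L))
})

test_that("argmax disagreement tracks the flip rate within 3 binomial SEs", {
  truth <- make_scene(scene_spec(height = 64L, width = 64L, seed = 6L))$truth
  rate <- 0.15
  dg <- degrade_spec(boundary_jitter_radius = 0L, label_flip_rate = rate,
                     seed = 7L)
  pm <- degrade_to_probmap(truth, dg)
  n <- length(truth)
  disagree <- mean(unclass(prob_argmax(pm)) != unclass(truth))
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(disagree - rate), 3 * se)
})

test_that("shattering yields class-pure segments that tile the frame", {
  set.seed(33)
  for (seed in c(1L, 12L, 123L)) {
    truth <- make_scene(scene_spec(height = 48L, width = 48L,
                                   seed = seed))$truth
    dg <- degrade_spec(segment_drop_rate = 0, seed = seed)
    stk <- shatter_to_segments(truth, dg)
    cover <- matrix(0L, 48L, 48L)
    for (s in stk$segments) {
      expect_length(unique(truth[s$mask]), 1L)   # purity
      expect_equal(s$area, sum(s$mask))
      cover <- cover + s$mask
    }
    expect_true(all(cover == 1L))                # exact tiling
    # scores clear the default filters by construction
    expect_true(all(vapply(stk$segments, `[[`, numeric(1),
                           "predicted_confidence") >= 0.92))
    expect_true(all(vapply(stk$segments, `[[`, numeric(1),
                           "stability") >= 0.88))
  }
})

test_that("segment splitting and dropping follow the spec parameters", {
  truth <- make_scene(scene_spec(height = 48L, width = 48L, seed = 8L))$truth
  # split_mean 0 -> one segment per connected region, still tiling
  dg0 <- degrade_spec(segment_split_mean = 0, segment_drop_rate = 0,
                      seed = 3L)
  stk0 <- shatter_to_segments(truth, dg0)
  n_regions <- 0L
  for (cls in 0:1) {
    comp <- EBImage::bwlabel((unclass(truth) == cls) * 1)
    n_regions <- n_regions + max(comp)
  }
  expect_equal(length(stk0), n_regions)

  # drop rate 1 with a huge area threshold removes every occlusion object
  dg1 <- degrade_spec(segment_drop_rate = 1,
                      min_dropped_object_area = 48L * 48L, seed = 3L)
  stk1 <- shatter_to_segments(truth, dg1)
  for (s in stk1$segments) expect_true(all(truth[s$mask] == 0L))

  # weak_scores exercises the filters
  dgw <- degrade_spec(weak_scores = TRUE, seed = 3L)
  stkw <- shatter_to_segments(truth, dgw)
  kept <- filter_segments(stkw, fusion_config())
  expect_lt(length(kept), length(stkw))
})

test_that("stress flag can inject boundary-crossing (impure) segments", {
  truth <- make_scene(scene_spec(height = 48L, width = 48L, seed = 8L))$truth
  stk <- shatter_to_segments(truth, degrade_spec(impure_rate = 1, seed = 2L))
  purity <- vapply(stk$segments, function(s)
    length(unique(truth[s$mask])) == 1L, logical(1))
  expect_false(all(purity))
  # fusion still runs and returns a valid mask
  pm <- degrade_to_probmap(truth, degrade_spec(seed = 2L))
  fused <- soss_fuse(pm, stk, fusion_config(uncovered_policy = "semantic_argmax"))
  expect_true(all(fused >= 0L & fused < 2L))
})

test_that("noiseless experiment gives identical perfect IoUs", {
  res <- improvement_experiment(
    scene_spec(height = 32L, width = 32L, seed = 1L),
    degrade_spec(boundary_jitter_radius = 0L, label_flip_rate = 0,
                 segment_drop_rate = 0, confidence_temperature = 0.01),
    n_seeds = 3L)
  expect_equal(res$iou_semantic, rep(1, 3))
  expect_equal(res$iou_fused, rep(1, 3))
})

test_that("a fully dropped object is missed under the background policy", {
  sp <- scene_spec(height = 48L, width = 48L, n_objects_range = c(1L, 1L),
                   object_kinds = "cable", seed = 14L)
  truth <- make_scene(sp)$truth
  dg <- degrade_spec(boundary_jitter_radius = 0L, label_flip_rate = 0,
                     segment_drop_rate = 1,
                     min_dropped_object_area = 48L * 48L, seed = 1L)
  pm <- degrade_to_probmap(truth, dg)
  stk <- shatter_to_segments(truth, dg)
  fused_bg <- soss_fuse(pm, stk, fusion_config(uncovered_policy = "background"))
  expect_true(all(fused_bg == 0L))         # proposal miss propagates
  sem <- prob_argmax(pm)
  expect_gt(sum(sem == 1L), 0L)            # the semantic map still sees it
})

test_that("fusion dominates the semantic baseline under majority-correct
           noise (sign test over seeds)", {
  res <- improvement_experiment(
    scene_spec(height = 64L, width = 64L, seed = 100L),
    degrade_spec(label_flip_rate = 0.2, boundary_jitter_radius = 1L,
                 segment_drop_rate = 0),
    n_seeds = 12L)
  wins <- sum(res$iou_fused > res$iou_semantic)
  p <- stats::binom.test(wins, nrow(res), alternative = "greater")$p.value
  expect_gt(mean(res$iou_fused), mean(res$iou_semantic))
  expect_lt(p, 0.05)
})
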