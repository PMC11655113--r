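---
title: "Soft-voting fusion of semantic and class-agnostic segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-voting fusion of semantic and class-agnostic segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sossr)
```

## The model

`sossr` addresses occlusion segmentation in camera-based patient
monitoring: tubes, cables, blankets and electrodes that obstruct the view
of the body must be segmented out before downstream vision tasks can run,
and labeled clinical imagery is too scarce to train a sharp segmenter. The
package fuses two complementary predictors:

- a **semantic probability map** `P_SEM` (`H × W × N`, class 0 =
  non-occlusion): coarse but labeled;
- a **segment stack** `P_SAM` (`O` binary masks with per-segment confidence
  and stability scores): sharp but unlabeled, possibly overlapping, and
  possibly covering only parts of objects.

The fusion rests on a class-purity assumption: any two pixels that a
proposal generator places in the same segment share the same hidden
occlusion class, i.e. `P(o_i = o_j | same segment) = 1`. Segments are then
the finest granularity the output needs, and labeling a segment reduces to
polling its pixels. For each surviving segment `S` the package computes the
per-class sum of the masked probabilities,

$$v_n = \sum_{(r,c) \in S} P_{SEM}[r,c,n], \qquad
  C = \arg\max_n v_n,$$

and writes `C` into all of `S`'s pixels. This is *soft* voting: each pixel
contributes its full probability vector (total influence bounded at 1)
rather than one hard vote, which tempers an overconfident semantic model —
a 0.51/0.49 pixel sways the poll far less than a 0.99/0.01 pixel. For any
segment the expected vote margin under independent per-pixel noise grows
linearly in segment area while its standard deviation grows as the square
root, so majority-correct segments are labeled correctly with probability
approaching 1 in their area — the mechanism the improvement experiment
(below) measures.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_confidence` | 0.90 | minimum generator-predicted mask quality, inclusive |
| `min_stability` | 0.85 | minimum stability score (insensitivity of the mask to logit thresholding), inclusive |
| `min_area` | 5 px | minimum segment area, inclusive; removes degenerate proposals |
| `n_per_side` | 40 | prompt grid resolution; 1600 cell-center points give the density needed for small occlusions |
| `uncovered_policy` | `background` | class for pixels no surviving segment covers; `semantic_argmax` falls back to the semantic map |
| `overlap_policy` | `smaller_wins` | segments composite in decreasing area order so fine-detail segments overwrite coarse ones |

All filter thresholds are inclusive (a segment at exactly 0.90/0.85/5 px
survives); this is the conventional reading of a stated threshold and is
pinned by tests. Tie-breaks in every argmax go to the lowest class id, so an
exact tie conservatively defaults to non-occlusion.

Two decisions were genuinely open and are this package's own choices:

- **Uncovered pixels.** Accumulating per-segment classes into an output
  raster leaves pixels outside every segment undefined. The default writes
  class 0 there, faithful to an all-zeros initialization — with the known
  consequence that a proposal miss (a thin cable the generator skipped)
  propagates to the output. `semantic_argmax` is offered because the
  semantic map often does see such objects; the synthetic experiment uses
  it.
- **Overlapping segments.** Sequential accumulation is order-dependent for
  overlapping proposals. `smaller_wins` applies segments in decreasing area
  order so smaller segments overwrite larger ones, preserving fine detail
  of thin or small objects; ties in area keep stack order. The evaluation
  semantics are identical for the hard labels and the soft scores, so the
  argmax of `fused_soft_scores()` equals `soss_fuse()` everywhere — a
  tested invariant.

## Evaluation semantics

Metrics are pixel-wise, one-vs-rest for a chosen class (default class 1,
the occlusion class of the binary task), restricted to an ROI when one is
given: `Acc = (TP+TN)/total`, `Prec = TP/(TP+FP)`, `Rec = TP/(TP+FN)`,
`F1 = 2TP/(2TP+FP+FN)`, `IoU = TP/(TP+FP+FN)`. Ratios that are 0/0 are
reported as `NaN` with a warning, never silently 0. AUC is the
threshold-sweep ROC area, computed as the Mann-Whitney statistic with
midranks (ties count ½) — exactly equivalent to trapezoidal integration
over all distinct thresholds, and checked in the tests against an
exhaustive pairwise oracle and against an independent ROC library. Multi-
image evaluation pools confusion counts before forming ratios
(pixel pooling, the default and what the report labels); per-image macro
averages are reported alongside because the two protocols genuinely differ
on unbalanced sets.

The AUC of a *fused* output is not well defined from hard labels alone;
`fused_soft_scores()` makes the package's choice explicit: each covered
pixel carries its segment's vote vector normalized by segment area, and
uncovered pixels keep their semantic probabilities (or the background
one-hot, per policy).

## The synthetic-data generator

Scenes (`make_scene()`) place 3–6 objects — elliptical blobs, rotated bars,
and random-walk cables dilated to a sampled thickness — on a background,
rendering each with a distinct mean color plus Gaussian noise (σ = 8 of
255). The defaults (128 × 128 frames in the experiment, binary classes)
keep the full improvement experiment fast while leaving objects large
enough to have meaningful boundaries; tests use 24–64 px frames for unit
checks and the stated 128 × 128 for the experiment.

Degradations are split by consumer:

- `degrade_to_probmap()` emulates the coarse semantic segmenter:
  per-object boundary dilation/erosion with random radius up to 2 px
  (over-smoothing; thin objects can vanish entirely under erosion — the
  over-representation/erasure failure mode of small-data segmenters), then
  i.i.d. label flips at rate 0.15, then temperature-softened one-hot
  encoding (`T = 0.25`; the winner gets `1/(1+(N−1)e^{−1/T})`, rows sum
  to 1, `T → 0` recovers hard labels). I.i.d. flips are deliberately the
  *weakest* noise under which per-segment majority voting provably helps:
  if fusion failed to dominate here, the mechanism itself would be suspect.
- `shatter_to_segments()` emulates the proposal generator: every
  4-connected truth region (background included — the generator partitions
  the whole frame) splits into `1 + Poisson(2)` nearest-seed pieces, so
  segments are class-pure by construction and tile the frame exactly
  (tested invariants). Confidence and stability are drawn from
  [0.92, 1] / [0.88, 1] so default filters pass; `weak_scores` draws from
  [0, 1] to exercise the filters, `impure_rate` dilates segments across
  truth boundaries to stress the purity assumption, and
  `segment_drop_rate` omits small occlusion objects entirely to reproduce
  the proposal-miss failure mode.

What the generator does **not** emulate: photorealistic clinical texture,
correlated (structured) segmenter errors, proposals that merge distinct
objects, camera noise, or class imbalance beyond what random scenes
produce. Passing tests therefore demonstrate the correctness and the noise-
removal mechanism of the fusion, not its performance on real ward imagery.

## Numerical and I/O choices

- **Rasterization.** Pixel `(r, c)` covers `[c, c+1) × [r, r+1)` with
  center `(c+0.5, r+0.5)`; a pixel belongs to a polygon iff its center is
  inside under the even-odd rule; the last-listed polygon wins overlaps.
  Label-Studio percent coordinates convert to pixels continuously — only
  rasterization discretizes, avoiding double rounding. The vectorized
  implementation is pinned to an exhaustive per-pixel oracle on random
  polygons.
- **Containers.** Label masks are single-channel PNGs (pixel value = class
  id; 8-bit up to 256 classes, 16-bit beyond — written by a small built-in
  encoder because the installed PNG bindings write 8-bit only). Segment
  stacks are one 0/255 PNG per segment plus a JSON manifest whose recorded
  areas are re-verified on read. Probability maps are JSON with values at
  17 significant digits, which round-trips IEEE doubles bit-exactly; all
  round-trips are tested for bit-exactness.
- **Degenerate inputs.** Empty stacks, empty filter results, all-background
  masks and empty annotation lists are legal; empty segments, empty ROIs,
  and single-class ROIs for AUC are validation errors.
- **Determinism.** Every generator is a pure function of its spec: seeds
  are applied in a scoped RNG context that restores the session stream, so
  the same spec is bit-identical regardless of surrounding code. The
  augmentation pipeline runs flips → photometric → copy-paste under one
  seeded stream per (seed, sample index).

## Known limitations

- The class-purity assumption is load-bearing: impure segments (crossing
  object boundaries) get a single class and smear errors across the
  boundary. The stress flag exists precisely to observe this degradation.
- With `uncovered_policy = "background"`, a proposal miss is an output
  miss; the package reproduces this failure mode by construction rather
  than hiding it.
- Metrics are pixel-level only; object-level detection metrics (mAP,
  panoptic quality) and boundary-distance metrics are out of scope, as are
  COCO run-length encodings and any neural inference — the package
  consumes segmenter *outputs*, it never runs a network.
- Augmentation magnitudes are conventional mid-strength defaults, all
  exposed in `augment_spec()`; nothing in the package depends on their
  particular values.
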