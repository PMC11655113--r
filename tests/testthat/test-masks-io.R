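# Annotation parsing, rasterization, ROI preprocessing and file round-trips.

write_labelstudio_fixture <- function(path, points_pct, label = "tube",
                                      ow = 8L, oh = 8L) {
  task <- list(list(
    id = 1L,
    data = list(image = "img_000.png"),
    annotations = list(list(result = list(list(
      type = "polygonlabels",
      original_width = ow, original_height = oh,
      value = list(points = points_pct,
                   polygonlabels = list(label))))))))
  jsonlite::write_json(task, path, auto_unbox = TRUE, digits = I(17))
  path
}

test_that("Label-Studio polygons parse with percent-to-pixel conversion", {
  f <- tempfile(fileext = ".json")
  # 4-vertex square at 12.5%..50% of an 8x8 original -> pixels 1..4
  write_labelstudio_fixture(f, list(c(12.5, 12.5), c(50, 12.5),
                                    c(50, 50), c(12.5, 50)))
  anns <- read_polygon_annotations(f, "labelstudio")
  expect_length(anns, 1L)
  expect_equal(nrow(anns[[1]]$vertices), 4L)
  expect_equal(anns[[1]]$vertices[, "x"], c(1, 4, 4, 1))
  expect_equal(anns[[1]]$vertices[, "y"], c(1, 1, 4, 4))
  expect_equal(anns[[1]]$class_id, 1L)
  expect_equal(anns[[1]]$image_id, "img_000.png")

  # class map routes label names to ids; unknown labels error
  anns2 <- read_polygon_annotations(f, "labelstudio",
                                    class_map = c(tube = 3L))
  expect_equal(anns2[[1]]$class_id, 3L)
  expect_error(read_polygon_annotations(f, "labelstudio",
                                        class_map = c(blanket = 2L)),
               "class_map")
})

test_that("degenerate and empty annotation files are handled", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(), f)
  expect_length(read_polygon_annotations(f, "labelstudio"), 0L)

  write_labelstudio_fixture(f, list(c(10, 10), c(50, 50)))
  expect_error(read_polygon_annotations(f, "labelstudio"), "need >= 3")

  writeLines("{not json", f)
  expect_error(read_polygon_annotations(f, "generic_json"), "malformed")
  expect_error(read_polygon_annotations(tempfile(), "generic_json"),
               "not found")
})

test_that("generic JSON dialect parses points and class ids", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(
    list(height = 8L, width = 8L,
         polygons = list(
           list(points = list(c(1, 1), c(4, 1), c(4, 4), c(1, 4)),
                class_id = 1L),
           list(points = list(c(0, 0), c(2, 0), c(0, 2)), class_id = 2L))),
    f, auto_unbox = TRUE)
  anns <- read_polygon_annotations(f, "generic_json")
  expect_length(anns, 2L)
  expect_equal(anns[[2]]$class_id, 2L)
  expect_equal(anns[[1]]$vertices[2, ], c(x = 4, y = 1))
})

test_that("axis-aligned square rasterizes to the 9 covered pixel centers", {
  a <- polygon_annotation(rbind(c(1, 1), c(4, 1), c(4, 4), c(1, 4)), 1L)
  m <- rasterize_polygons(list(a), 8L, 8L)
  expect_equal(sum(m == 1L), 9L)
  # centers at x,y in {1.5, 2.5, 3.5} -> rows/cols 2:4 (1-based)
  expect_true(all(m[2:4, 2:4] == 1L))
  expect_equal(sum(m), 9L)
})

test_that("no annotations give an all-zero mask; last polygon wins overlap", {
  expect_true(all(rasterize_polygons(list(), 5L, 5L) == 0L))
  sq <- function(cls) polygon_annotation(
    rbind(c(0, 0), c(5, 0), c(5, 5), c(0, 5)), cls)
  m <- rasterize_polygons(list(sq(1L), sq(2L)), 8L, 8L, n_classes = 3L)
  expect_true(all(m[1:5, 1:5] == 2L))
  expect_error(rasterize_polygons(list(sq(2L)), 8L, 8L, n_classes = 2L),
               "n_classes")
  far <- polygon_annotation(rbind(c(100, 0), c(101, 0), c(100, 1)), 1L)
  expect_error(rasterize_polygons(list(far), 8L, 8L), "outside")
})

test_that("rasterization matches the exhaustive pixel-center oracle", {
  set.seed(42)
  for (rep in 1:25) {
    h <- sample(4:32, 1L); w <- sample(4:32, 1L)
    anns <- lapply(seq_len(sample(1:3, 1L)), function(i) {
      nv <- sample(3:8, 1L)
      polygon_annotation(cbind(stats::runif(nv, -2, w + 2),
                               stats::runif(nv, -2, h + 2)),
                         class_id = sample(1:3, 1L))
    })
    got <- rasterize_polygons(anns, h, w, n_classes = 4L)
    expect_same_labels(got, oracle_rasterize(anns, h, w))
  }
})

test_that("crop_and_pad centers content and pads by kind", {
  m <- label_mask(matrix(1L, 10L, 10L), 2L)
  out <- crop_and_pad(m, roi(2L, 8L, 2L, 8L), c(8L, 8L))
  expect_equal(dim(out), c(8L, 8L))
  expect_true(all(out[2:7, 2:7] == 1L))
  expect_true(all(out[1, ] == 0L) && all(out[, 1] == 0L) &&
              all(out[8, ] == 0L) && all(out[, 8] == 0L))

  # identity when roi covers the full frame and target equals the extent
  ident <- crop_and_pad(m, roi(0L, 10L, 0L, 10L), c(10L, 10L))
  expect_same_labels(ident, m)

  # probability padding is one-hot background
  p <- rand_probs(6L, 6L, 3L)
  pp <- crop_and_pad(p, roi(1L, 5L, 1L, 5L), c(8L, 8L))
  expect_equal(pp[1, 1, ], c(1, 0, 0))
  expect_equal(dim(pp), c(8L, 8L, 3L))

  # image padding is black
  img <- array(200, c(6L, 6L, 3L))
  pi <- crop_and_pad(img, roi(0L, 6L, 0L, 6L), c(8L, 8L))
  expect_equal(pi[1, 1, ], c(0, 0, 0))

  expect_error(crop_and_pad(m, roi(0L, 10L, 0L, 10L), c(8L, 8L)), "smaller")
})

test_that("crop_and_pad followed by uncrop recovers the ROI content", {
  set.seed(7)
  m <- label_mask(matrix(sample(0:2, 100L, TRUE), 10L, 10L), 3L)
  r <- roi(1L, 9L, 3L, 10L)
  out <- crop_and_pad(m, r, c(12L, 11L))
  expect_identical(uncrop(out, r)[, ],
                   unclass(m)[roi_rows(r), roi_cols(r)])
})

test_that("label-mask PNG round-trips are bit-exact at both bit depths", {
  set.seed(11)
  m8 <- label_mask(matrix(sample(0:3, 48L, TRUE), 6L, 8L), 4L)
  f <- tempfile(fileext = ".png")
  write_label_mask(m8, f)
  expect_same_labels(read_label_mask(f, 4L), m8)

  m16 <- label_mask(matrix(sample(0:400, 48L, TRUE), 6L, 8L), 500L)
  write_label_mask(m16, f)
  expect_same_labels(read_label_mask(f, 500L), m16)

  # class count enforced on read
  write_label_mask(m8, f)
  expect_error(read_label_mask(f, n_classes = 2L), "exceeds")

  # multi-channel PNGs are rejected
  frgb <- tempfile(fileext = ".png")
  png::writePNG(array(0.5, c(4L, 4L, 3L)), frgb)
  expect_error(read_label_mask(frgb), "single-channel")
})

test_that("segment-stack directory round-trips and manifest integrity", {
  set.seed(5)
  stk <- rand_stack(6L, 6L, 3L)
  while (length(stk) == 0L) stk <- rand_stack(6L, 6L, 3L)
  d <- tempfile()
  write_segment_stack(stk, d)
  expect_identical(read_segment_stack(d), stk)

  # corrupt the manifest area -> integrity error
  mf <- file.path(d, "manifest.json")
  man <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  man$segments[[1]]$area <- man$segments[[1]]$area + 1L
  jsonlite::write_json(man, mf, auto_unbox = TRUE, digits = I(17))
  expect_error(read_segment_stack(d), "area")

  # empty stack round-trips
  d2 <- tempfile()
  empty <- segment_stack(list(), height = 4L, width = 5L)
  write_segment_stack(empty, d2)
  back <- read_segment_stack(d2)
  expect_length(back, 0L)
  expect_equal(c(back$height, back$width), c(4L, 5L))

  # missing mask file
  unlink(list.files(d, pattern = "segment_0000", full.names = TRUE))
  jsonlite::write_json(jsonlite::fromJSON(mf, simplifyVector = FALSE), mf,
                       auto_unbox = TRUE, digits = I(17))
  expect_error(read_segment_stack(d), "missing")
})

test_that("probability-map JSON container round-trips bit-exactly", {
  set.seed(3)
  p <- rand_probs(5L, 7L, 3L)
  f <- tempfile(fileext = ".json")
  write_prob_map(p, f)
  back <- read_prob_map(f)
  expect_identical(c(unclass(back)), c(unclass(p)))
  expect_equal(dim(back), dim(p))
})
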