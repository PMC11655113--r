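# Annotation, raster and segment-stack I/O plus the labeling-stage
# preprocessing (polygon rasterization, ROI crop/pad).

#' Read polygon annotations from JSON
#'
#' Supports two dialects. `labelstudio` parses a Label-Studio JSON export:
#' polygon results carry vertices as percentages of the original image size,
#' which are converted to absolute pixel coordinates (continuously — only
#' rasterization discretizes). `generic_json` parses
#' `{"polygons": [{"points": [[x, y], ...], "class_id": k}], "height": H,
#' "width": W}` with pixel coordinates.
#'
#' @param path JSON file.
#' @param dialect `"labelstudio"` or `"generic_json"`.
#' @param class_map Named integer vector mapping Label-Studio label names to
#'   class ids `>= 1`. With the default `NULL` every polygon maps to class 1
#'   (binary occlusion). Unknown labels are an error. Ignored by
#'   `generic_json`.
#' @return List of [polygon_annotation()] objects, in file order.
#' @export
read_polygon_annotations <- function(path,
                                     dialect = c("labelstudio", "generic_json"),
                                     class_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stopf("malformed JSON in %s: %s", path, conditionMessage(e)))
  if (dialect == "generic_json") parse_generic_polygons(doc, path)
  else parse_labelstudio_polygons(doc, path, class_map)
}

parse_generic_polygons <- function(doc, path) {
  polys <- doc$polygons
  if (is.null(polys)) stopf("%s: missing \"polygons\" field", path)
  out <- vector("list", length(polys))
  for (i in seq_along(polys)) {
    p <- polys[[i]]
    pts <- p$points
    if (is.null(pts) || length(pts) < 3L)
      stopf("%s: polygon %d has %d point(s); need >= 3", path, i,
            length(pts))
    v <- t(vapply(pts, function(q) as.numeric(unlist(q)[1:2]), numeric(2L)))
    cid <- if (is.null(p$class_id)) 1L else p$class_id
    out[[i]] <- polygon_annotation(v, cid,
                                   image_id = if (is.null(doc$image_id)) ""
                                              else doc$image_id)
  }
  out
}

parse_labelstudio_polygons <- function(doc, path, class_map) {
  out <- list()
  for (ti in seq_along(doc)) {
    task <- doc[[ti]]
    img <- if (!is.null(task$data$image)) as.character(task$data$image)
           else if (!is.null(task$id)) as.character(task$id) else ""
    anns <- task$annotations
    if (is.null(anns)) anns <- task$completions  # older export name
    for (ann in anns) for (res in ann$result) {
      if (!identical(res$type, "polygonlabels")) next
      ow <- res$original_width; oh <- res$original_height
      if (is.null(ow) || is.null(oh))
        stopf("%s: task %d polygon misses original image size", path, ti)
      pts <- res$value$points
      if (is.null(pts) || length(pts) < 3L)
        stopf("%s: task %d has a polygon with %d point(s); need >= 3",
              path, ti, length(pts))
      # percent of original size -> absolute pixels, no rounding
      v <- t(vapply(pts, function(q) as.numeric(unlist(q)[1:2]), numeric(2L)))
      v[, 1L] <- v[, 1L] / 100 * as.numeric(ow)
      v[, 2L] <- v[, 2L] / 100 * as.numeric(oh)
      lab <- unlist(res$value$polygonlabels)[1L]
      cid <- if (is.null(class_map)) 1L
             else if (!is.null(lab) && lab %in% names(class_map))
               as.integer(class_map[[lab]])
             else stopf("%s: label \"%s\" missing from class_map", path, lab)
      out[[length(out) + 1L]] <- polygon_annotation(v, cid, image_id = img)
    }
  }
  out
}

# Even-odd point-in-polygon crossing test, vectorized over query points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize polygon annotations to a label mask
#'
#' A pixel takes the class of the last-listed polygon whose interior (even-odd
#' rule) contains the pixel center `(c + 0.5, r + 0.5)`; pixels inside no
#' polygon get class 0.
#'
#' @param annotations List of [polygon_annotation()] objects.
#' @param height,width Output extent in pixels.
#' @param n_classes Class count; must exceed every annotation's class id.
#' @return A [label_mask()].
#' @export
rasterize_polygons <- function(annotations, height, width, n_classes = 2L) {
  height <- as.integer(height); width <- as.integer(width)
  n_classes <- as.integer(n_classes)
  labels <- matrix(0L, height, width)
  # centers: x along columns, y along rows
  cx <- rep(seq_len(width) - 0.5, each = height)
  cy <- rep(seq_len(height) - 0.5, width)
  for (i in seq_along(annotations)) {
    a <- annotations[[i]]
    if (!inherits(a, "polygon_annotation")) stopf("annotation %d: wrong type", i)
    if (a$class_id >= n_classes)
      stopf("annotation %d: class_id %d needs n_classes > %d",
            i, a$class_id, a$class_id)
    v <- a$vertices
    tol_x <- c(-width, 2 * width); tol_y <- c(-height, 2 * height)
    if (min(v[, 1L]) < tol_x[1L] || max(v[, 1L]) > tol_x[2L] ||
        min(v[, 2L]) < tol_y[1L] || max(v[, 2L]) > tol_y[2L])
      stopf("annotation %d: vertex far outside the image frame", i)
    inside <- points_in_polygon(cx, cy, v[, 1L], v[, 2L])
    labels[matrix(inside, height, width)] <- a$class_id
  }
  label_mask(labels, n_classes)
}

#' Crop a raster to an ROI and pad it to a target extent
#'
#' The labeling-stage preprocessing: the raster is cropped to `roi`, then
#' padded symmetrically (extra pixel, if any, on the bottom/right) to
#' `target`. Label masks pad with class 0, probability maps with the one-hot
#' of class 0, images with black.
#'
#' @param raster A `label_mask`, `prob_map`, or numeric image array
#'   (`H x W` or `H x W x channels`).
#' @param roi A [roi()]; cropping happens first.
#' @param target `c(height, width)` of the output; must be at least the ROI
#'   extent.
#' @return A raster of the same kind with extent `target`.
#' @export
crop_and_pad <- function(raster, roi, target) {
  is_lab <- inherits(raster, "label_mask")
  is_prob <- inherits(raster, "prob_map")
  h <- dim(raster)[1L]; w <- dim(raster)[2L]
  roi_check(roi, h, w)
  ch <- roi$row_end - roi$row_start; cw <- roi$col_end - roi$col_start
  th <- as.integer(target[1L]); tw <- as.integer(target[2L])
  if (th < ch || tw < cw)
    stopf("target %dx%d smaller than roi extent %dx%d", th, tw, ch, cw)
  top <- (th - ch) %/% 2L; left <- (tw - cw) %/% 2L
  rr <- roi_rows(roi); cc <- roi_cols(roi)
  or <- top + seq_len(ch); oc <- left + seq_len(cw)
  if (is_lab) {
    out <- matrix(0L, th, tw)
    out[or, oc] <- raster[rr, cc]
    return(label_mask(out, n_classes(raster)))
  }
  if (is_prob) {
    nc <- dim(raster)[3L]
    out <- array(0, c(th, tw, nc))
    out[, , 1L] <- 1  # one-hot background
    out[or, oc, ] <- raster[rr, cc, , drop = FALSE]
    return(prob_map(out))
  }
  if (length(dim(raster)) == 3L) {
    out <- array(0, c(th, tw, dim(raster)[3L]))
    out[or, oc, ] <- raster[rr, cc, , drop = FALSE]
  } else {
    out <- matrix(0, th, tw)
    out[or, oc] <- raster[rr, cc]
  }
  out
}

#' Invert a crop-and-pad: recover the ROI content
#'
#' @param raster Output of [crop_and_pad()].
#' @param roi The [roi()] used for the crop.
#' @return The cropped content (the ROI-sized sub-raster).
#' @export
uncrop <- function(raster, roi) {
  ch <- roi$row_end - roi$row_start; cw <- roi$col_end - roi$col_start
  th <- dim(raster)[1L]; tw <- dim(raster)[2L]
  top <- (th - ch) %/% 2L; left <- (tw - cw) %/% 2L
  if (length(dim(raster)) == 3L)
    raster[top + seq_len(ch), left + seq_len(cw), , drop = FALSE]
  else raster[top + seq_len(ch), left + seq_len(cw), drop = FALSE]
}

#' Write / read a label mask as single-channel PNG
#'
#' Pixel value equals the class id. Masks with up to 256 classes are written
#' as 8-bit grayscale; larger class counts use 16-bit grayscale. Round-trips
#' are bit-exact.
#'
#' @param mask A [label_mask()].
#' @param path PNG file path.
#' @return `write_label_mask` returns `path` invisibly; `read_label_mask`
#'   returns a [label_mask()].
#' @export
write_label_mask <- function(mask, path) {
  if (!inherits(mask, "label_mask")) stopf("`mask` must be a label_mask")
  if (n_classes(mask) <= 256L) {
    png::writePNG(unclass(mask) / 255, path)
  } else {
    png_write_gray16(unclass(mask), path)
  }
  invisible(path)
}

#' @param n_classes Expected class count; `NULL` infers
#'   `max(2, max(value) + 1)`. Values `>= n_classes` are an error.
#' @rdname write_label_mask
#' @export
read_label_mask <- function(path, n_classes = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) != 2L)
    stopf("%s: label masks must be single-channel, got %s", path,
          info$color.type)
  vals <- round(img * (2^info$bit.depth - 1))
  if (is.null(n_classes)) n_classes <- max(2, max(vals) + 1)
  if (max(vals) >= n_classes)
    stopf("%s: pixel value %d exceeds n_classes %d", path, max(vals),
          n_classes)
  label_mask(matrix(as.integer(vals), nrow(vals), ncol(vals)), n_classes)
}

#' Write / read a segment stack as a directory
#'
#' Persistence format for automatic-mask-generator output so real segmenter
#' runs can be ingested offline: one 8-bit 0/255 PNG per segment plus a
#' `manifest.json` recording, in stack order, each segment's file name,
#' predicted confidence, stability and area. On read the manifest area must
#' equal the mask's recomputed area.
#'
#' @param stack A [segment_stack()].
#' @param dir_path Directory (created if missing).
#' @return `write_segment_stack` returns `dir_path` invisibly;
#'   `read_segment_stack` returns a [segment_stack()].
#' @export
write_segment_stack <- function(stack, dir_path) {
  if (!inherits(stack, "segment_stack")) stopf("`stack` must be a segment_stack")
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  n <- length(stack$segments)
  files <- sprintf("segment_%04d.png", seq_len(n) - 1L)
  for (i in seq_len(n))
    png::writePNG((stack$segments[[i]]$mask) * 1, file.path(dir_path, files[i]))
  manifest <- list(
    height = stack$height, width = stack$width,
    segments = lapply(seq_len(n), function(i) {
      s <- stack$segments[[i]]
      list(file = files[i], predicted_confidence = s$predicted_confidence,
           stability = s$stability, area = s$area)
    }))
  jsonlite::write_json(manifest, file.path(dir_path, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir_path)
}

#' @rdname write_segment_stack
#' @export
read_segment_stack <- function(dir_path) {
  mf <- file.path(dir_path, "manifest.json")
  if (!file.exists(mf)) stopf("missing manifest: %s", mf)
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  n <- length(manifest$segments)
  masks <- vector("list", n); conf <- numeric(n); stab <- numeric(n)
  for (i in seq_len(n)) {
    rec <- manifest$segments[[i]]
    fp <- file.path(dir_path, rec$file)
    if (!file.exists(fp)) stopf("manifest names missing mask file: %s", fp)
    m <- round(png::readPNG(fp) * 255) > 127
    if (sum(m) != rec$area)
      stopf("%s: manifest area %d but mask has %d set pixels",
            rec$file, rec$area, sum(m))
    masks[[i]] <- m
    conf[i] <- rec$predicted_confidence; stab[i] <- rec$stability
  }
  segment_stack(masks, conf, stab,
                height = manifest$height, width = manifest$width)
}

#' Write / read a probability map as a JSON container
#'
#' A portable text container: a header (`height`, `width`, `n_classes`) plus
#' the probabilities flattened row-major (row, then column, then class) at
#' full double precision, so round-trips are bit-exact.
#'
#' @param probs A [prob_map()].
#' @param path JSON file path.
#' @return `write_prob_map` returns `path` invisibly; `read_prob_map`
#'   returns a [prob_map()].
#' @export
write_prob_map <- function(probs, path) {
  if (!inherits(probs, "prob_map")) stopf("`probs` must be a prob_map")
  d <- dim(probs)
  # flatten row-major: class fastest, then column, then row
  flat <- as.vector(aperm(unclass(probs), c(3L, 2L, 1L)))
  jsonlite::write_json(
    list(height = d[1L], width = d[2L], n_classes = d[3L], probs = flat),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_prob_map
#' @export
read_prob_map <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- jsonlite::fromJSON(path)
  d <- c(doc$height, doc$width, doc$n_classes)
  if (length(doc$probs) != prod(d))
    stopf("%s: expected %d values, found %d", path, prod(d),
          length(doc$probs))
  probs <- aperm(array(doc$probs, c(d[3L], d[2L], d[1L])), c(3L, 2L, 1L))
  prob_map(probs)
}

#' Write / read an RGB image as PNG
#'
#' Images are `H x W x 3` arrays with channel values in `[0, 255]`.
#'
#' @param image Image array.
#' @param path PNG file path.
#' @return `write_image` returns `path` invisibly; `read_image` the array.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3L] == 4L)
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  round(img * 255)
}
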