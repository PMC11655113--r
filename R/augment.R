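# Paired image + mask augmentations with deterministic seeding: geometric
# flips, photometric jitter, and a copy-paste transform that moves whole
# connected occlusion components between scenes. One ordered pipeline
# (geometric -> photometric -> copy-paste) driven by a single seeded
# generator keeps every augmented sample replayable.

#' Augmentation configuration
#'
#' Magnitudes are conventional mid-strength defaults (the transform families
#' are fixed, their strengths are tunable): channel values are on the
#' `[0, 255]` scale, hue is on the `[0, 1]` wheel.
#'
#' @param hflip_prob,vflip_prob Flip probabilities.
#' @param brightness_delta_range Additive brightness range (of 255).
#' @param contrast_factor_range Multiplicative contrast range about each
#'   channel's mean.
#' @param hue_delta_range Additive hue rotation range.
#' @param saturation_factor_range Multiplicative saturation range.
#' @param copy_paste_prob Probability of applying copy-paste.
#' @param copy_paste_max_instances Components pasted per application.
#' @param seed Pipeline RNG seed.
#' @return An `augment_spec`.
#' @export
augment_spec <- function(hflip_prob = 0.5, vflip_prob = 0.25,
                         brightness_delta_range = c(-32, 32),
                         contrast_factor_range = c(0.8, 1.2),
                         hue_delta_range = c(-0.05, 0.05),
                         saturation_factor_range = c(0.8, 1.2),
                         copy_paste_prob = 0.5,
                         copy_paste_max_instances = 3L,
                         seed = 0L) {
  probs <- c(hflip_prob, vflip_prob, copy_paste_prob)
  if (anyNA(probs) || min(probs) < 0 || max(probs) > 1)
    stopf("probabilities must lie in [0, 1]")
  for (r in list(brightness_delta_range, contrast_factor_range,
                 hue_delta_range, saturation_factor_range))
    if (length(r) != 2L || r[1L] > r[2L]) stopf("ranges must be ordered pairs")
  structure(list(hflip_prob = hflip_prob, vflip_prob = vflip_prob,
                 brightness_delta_range = brightness_delta_range,
                 contrast_factor_range = contrast_factor_range,
                 hue_delta_range = hue_delta_range,
                 saturation_factor_range = saturation_factor_range,
                 copy_paste_prob = copy_paste_prob,
                 copy_paste_max_instances = as.integer(copy_paste_max_instances),
                 seed = as.integer(seed)),
            class = "augment_spec")
}

flip_raster <- function(x, axis) {
  if (length(dim(x)) == 3L) {
    if (axis == "horizontal") x[, ncol(x):1, , drop = FALSE]
    else x[nrow(x):1, , , drop = FALSE]
  } else {
    if (axis == "horizontal") x[, ncol(x):1, drop = FALSE]
    else x[nrow(x):1, , drop = FALSE]
  }
}

#' Flip an image and its mask together
#'
#' `"horizontal"` mirrors left-right (columns), `"vertical"` top-bottom
#' (rows). Applying the same flip twice is the identity.
#'
#' @param image Numeric image array (`H x W` or `H x W x C`).
#' @param mask A [label_mask()] of the same extent.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return List with flipped `image` and `mask`.
#' @export
flip_pair <- function(image, mask, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  if (!all(dim(image)[1:2] == dim(mask)))
    stopf("image %dx%d and mask %dx%d differ in extent",
          dim(image)[1L], dim(image)[2L], nrow(mask), ncol(mask))
  nc <- n_classes(mask)
  list(image = flip_raster(image, axis),
       mask = label_mask(flip_raster(unclass(mask), axis), nc))
}

#' Photometric jitter of an image
#'
#' Per channel: `clip(contrast * (x - mean(channel)) + mean(channel) +
#' brightness)`, followed by hue rotation and saturation scaling in HSV
#' space; the mask is untouched by construction. Magnitudes are drawn
#' uniformly from the spec's ranges using the current RNG state. A spec with
#' zero deltas and unit factors returns the image unchanged.
#'
#' @param image `H x W x 3` array, channels in `[0, 255]`.
#' @param spec An [augment_spec()].
#' @return The jittered image, clipped to `[0, 255]`.
#' @export
photometric <- function(image, spec = augment_spec()) {
  runif1 <- function(r) if (r[1L] == r[2L]) r[1L] else stats::runif(1, r[1L], r[2L])
  bright <- runif1(spec$brightness_delta_range)
  contrast <- runif1(spec$contrast_factor_range)
  hue <- runif1(spec$hue_delta_range)
  sat <- runif1(spec$saturation_factor_range)
  out <- image
  if (contrast != 1 || bright != 0) {
    for (ch in seq_len(dim(out)[3L])) {
      m <- mean(out[, , ch])
      out[, , ch] <- contrast * (out[, , ch] - m) + m + bright
    }
    out <- pmin(pmax(out, 0), 255)
  }
  if (hue != 0 || sat != 1) {
    d <- dim(out)
    rgb <- t(matrix(out, d[1L] * d[2L], 3L))
    hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
    hsv[1L, ] <- (hsv[1L, ] + hue) %% 1
    hsv[2L, ] <- pmin(pmax(hsv[2L, ] * sat, 0), 1)
    back <- grDevices::col2rgb(grDevices::hsv(hsv[1L, ], hsv[2L, ], hsv[3L, ]))
    out <- array(as.numeric(t(back)), d)
  }
  out
}

#' Copy-paste augmentation
#'
#' Samples up to `max_instances` 4-connected occlusion components (class
#' `>= 1`) uniformly without replacement from the source mask, translates
#' each by a uniform random in-bounds offset, and composites it onto the
#' destination: pasted pixels take the source image values and source
#' classes, overwriting whatever was beneath. A source with no occlusion
#' component yields the destination unchanged, with a notice.
#'
#' @param src_image,src_mask Source pair (image array + [label_mask()]).
#' @param dst_image,dst_mask Destination pair of the same extent.
#' @param max_instances Maximum components to paste.
#' @param offsets Optional list of fixed `(row, col)` translations, one per
#'   pasted component, overriding the random in-bounds offsets (useful to
#'   reproduce a specific composition).
#' @return List with the composited `image` and `mask`.
#' @export
copy_paste <- function(src_image, src_mask, dst_image, dst_mask,
                       max_instances = 3L, offsets = NULL) {
  if (!all(dim(src_mask) == dim(dst_mask)))
    stopf("source and destination extents differ")
  nc <- max(n_classes(src_mask), n_classes(dst_mask))
  out_img <- dst_image
  out_lab <- matrix(as.integer(unclass(dst_mask)), nrow(dst_mask),
                    ncol(dst_mask))
  max_instances <- as.integer(max_instances)
  if (max_instances < 1L)
    return(list(image = out_img, mask = label_mask(out_lab, nc)))
  comp <- EBImage::bwlabel((unclass(src_mask) > 0L) * 1)
  ids <- setdiff(sort(unique(as.vector(comp))), 0)
  if (length(ids) == 0L) {
    message("copy_paste: source has no occlusion component; skipping")
    return(list(image = out_img, mask = label_mask(out_lab, nc)))
  }
  take <- if (length(ids) == 1L) ids else
    sample(ids, min(max_instances, length(ids)))
  h <- nrow(out_lab); w <- ncol(out_lab)
  for (k in seq_along(take)) {
    id <- take[k]
    px <- which(comp == id, arr.ind = TRUE)
    r0 <- min(px[, 1L]); r1 <- max(px[, 1L])
    c0 <- min(px[, 2L]); c1 <- max(px[, 2L])
    if (!is.null(offsets)) {
      dr <- as.integer(offsets[[k]][1L]); dc <- as.integer(offsets[[k]][2L])
    } else {
      dr <- sample.int(h - (r1 - r0), 1L) - r0      # keeps rows in [1, h]
      dc <- sample.int(w - (c1 - c0), 1L) - c0
    }
    dest <- cbind(px[, 1L] + dr, px[, 2L] + dc)
    out_lab[dest] <- unclass(src_mask)[px]
    for (ch in seq_len(dim(out_img)[3L]))
      out_img[cbind(dest, ch)] <- src_image[cbind(px, ch)]
  }
  list(image = out_img, mask = label_mask(out_lab, nc))
}

#' Apply the full augmentation pipeline to one sample
#'
#' Fixed order — flips, then photometric jitter, then copy-paste — under one
#' seeded generator, so a given `(spec$seed, sample_index)` always produces
#' bit-identical output.
#'
#' @param image,mask The sample to augment.
#' @param spec An [augment_spec()].
#' @param paste_pool Optional list of `list(image =, mask =)` source pairs
#'   for copy-paste; `NULL` disables the transform.
#' @param sample_index Index decorrelating the stream across samples.
#' @return List with augmented `image` and `mask`.
#' @export
augment_pipeline <- function(image, mask, spec = augment_spec(),
                             paste_pool = NULL, sample_index = 1L) {
  with_seed(spec$seed + 1000003L * as.integer(sample_index), {
    if (stats::runif(1) < spec$hflip_prob) {
      fl <- flip_pair(image, mask, "horizontal")
      image <- fl$image; mask <- fl$mask
    }
    if (stats::runif(1) < spec$vflip_prob) {
      fl <- flip_pair(image, mask, "vertical")
      image <- fl$image; mask <- fl$mask
    }
    image <- photometric(image, spec)
    if (!is.null(paste_pool) && length(paste_pool) > 0L &&
        stats::runif(1) < spec$copy_paste_prob) {
      src <- paste_pool[[sample.int(length(paste_pool), 1L)]]
      cp <- copy_paste(src$image, src$mask, image, mask,
                       spec$copy_paste_max_instances)
      image <- cp$image; mask <- cp$mask
    }
    list(image = image, mask = mask)
  })
}
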