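# Pixel normalization and the affine augmentation pipeline: rotation, width/
# height shift, horizontal shear, isotropic zoom, horizontal flip, composed
# into a single matrix and applied in one inverse-mapped bilinear resampling
# pass with nearest-pixel ("replicate") fill outside the source domain.

#' Normalize raw pixels to `[-1, 1]`
#'
#' Applies `x / 127.5 - 1` elementwise: 0 maps to -1, 127.5 to 0, 255 to +1.
#' Linear, hence order- and ratio-preserving.
#'
#' @param img Raw-range image array (values in `[0, 255]`).
#' @return Image array with `range = "normalized"`.
#' @export
preprocess_pixels <- function(img) {
  assert_raw_range(img)
  out <- img / 127.5 - 1
  image_array(unclass(out), range = "normalized")
}

#' Augmentation parameter ranges
#'
#' Default ranges: rotation up to ±20 degrees, shifts up to ±0.2 of the image
#' side, shear up to ±0.2, zoom in `[0.8, 1.2]`, horizontal flip with
#' probability 0.5, nearest fill.
#'
#' @param rotation_range Max absolute rotation, degrees.
#' @param width_shift_range,height_shift_range Max absolute shift fraction.
#' @param shear_range Max absolute shear coefficient.
#' @param zoom_range Zoom half-range `d`: zoom drawn from `[1 - d, 1 + d]`.
#' @param horizontal_flip Enable random horizontal flips?
#' @param fill_mode Only `"nearest"` is implemented.
#' @return An `augment_ranges` list.
#' @export
augment_ranges <- function(rotation_range = 20,
                           width_shift_range = 0.2,
                           height_shift_range = 0.2,
                           shear_range = 0.2,
                           zoom_range = 0.2,
                           horizontal_flip = TRUE,
                           fill_mode = "nearest") {
  if (!identical(fill_mode, "nearest")) {
    abort("Only fill_mode = \"nearest\" is supported.", class = "sobelnet_error_validation")
  }
  structure(list(
    rotation_range = rotation_range, width_shift_range = width_shift_range,
    height_shift_range = height_shift_range, shear_range = shear_range,
    zoom_range = zoom_range, horizontal_flip = isTRUE(horizontal_flip),
    fill_mode = fill_mode
  ), class = "augment_ranges")
}

#' Draw one set of augmentation parameters
#'
#' Uniform draws within each range and a Bernoulli(0.5) flip, from the
#' current RNG stream (seed with [set.seed()] or [withr::with_seed()] for
#' reproducibility).
#'
#' @param ranges An [augment_ranges()].
#' @return An `augment_params` list: `rotation_deg`, `shift_x`, `shift_y`,
#'   `shear`, `zoom`, `flip`.
#' @export
sample_params <- function(ranges = augment_ranges()) {
  p <- list(
    rotation_deg = runif(1, -ranges$rotation_range, ranges$rotation_range),
    shift_x = runif(1, -ranges$width_shift_range, ranges$width_shift_range),
    shift_y = runif(1, -ranges$height_shift_range, ranges$height_shift_range),
    shear = runif(1, -ranges$shear_range, ranges$shear_range),
    zoom = runif(1, 1 - ranges$zoom_range, 1 + ranges$zoom_range),
    flip = ranges$horizontal_flip && (runif(1) < 0.5)
  )
  structure(p, class = "augment_params")
}

#' Identity augmentation parameters
#' @return An `augment_params` with no rotation, shift, shear, unit zoom, no flip.
#' @export
identity_params <- function() {
  structure(list(rotation_deg = 0, shift_x = 0, shift_y = 0, shear = 0,
    zoom = 1, flip = FALSE), class = "augment_params")
}

# Homogeneous 3x3 forward coordinate maps, x = column, y = row, 0-based,
# linear parts acting about the image center.
affine_matrix <- function(p, H, W) {
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  center <- function(M) {
    Tm <- diag(3); Tm[1, 3] <- -cx; Tm[2, 3] <- -cy
    Tb <- diag(3); Tb[1, 3] <- cx; Tb[2, 3] <- cy
    Tb %*% M %*% Tm
  }
  th <- p$rotation_deg * pi / 180
  rot <- center(matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3))
  shift <- diag(3); shift[1, 3] <- p$shift_x * W; shift[2, 3] <- p$shift_y * H
  shear <- center(matrix(c(1, 0, 0, p$shear, 1, 0, 0, 0, 1), 3, 3)) # x' = x + shear * y
  zoom <- center(diag(c(p$zoom, p$zoom, 1)))
  flip <- if (p$flip) {
    m <- diag(3); m[1, 1] <- -1; m[1, 3] <- W - 1; m
  } else diag(3)
  flip %*% zoom %*% shear %*% shift %*% rot
}

#' Apply a composed affine transform to an image
#'
#' Composition order is flip ∘ zoom ∘ shear ∘ shift ∘ rotate, realised as a
#' single composed matrix and one inverse-mapped bilinear resampling pass.
#' Source coordinates outside the image are clamped to the border
#' (nearest-pixel fill). Identity parameters return the input exactly; a
#' pure flip is an exact pixel permutation.
#'
#' @param img Image array (raw or normalized; the range tag is preserved).
#' @param p An `augment_params` (see [sample_params()]).
#' @return Transformed image array of the same shape and range.
#' @export
apply_affine <- function(img, p) {
  if (p$zoom <= 0) abort("Zoom factor must be > 0.", class = "sobelnet_error_validation")
  rng <- img_range(img)
  two_d <- length(dim(img)) == 2L
  if (two_d) img <- array(img, dim = c(dim(img), 1L))
  H <- dim(img)[1L]; W <- dim(img)[2L]; C <- dim(img)[3L]

  exact_identity <- p$rotation_deg == 0 && p$shift_x == 0 && p$shift_y == 0 &&
    p$shear == 0 && p$zoom == 1
  if (exact_identity && !p$flip) {
    out <- img
  } else if (exact_identity && p$flip) {
    out <- img[, W:1, , drop = FALSE]
  } else {
    Minv <- solve(affine_matrix(p, H, W))
    xd <- rep(0:(W - 1), each = H)
    yd <- rep(0:(H - 1), times = W)
    xs <- Minv[1, 1] * xd + Minv[1, 2] * yd + Minv[1, 3]
    ys <- Minv[2, 1] * xd + Minv[2, 2] * yd + Minv[2, 3]
    # nearest fill == clamp source coordinates to the valid domain
    xs <- pmin(pmax(xs, 0), W - 1)
    ys <- pmin(pmax(ys, 0), H - 1)
    x0 <- floor(xs); y0 <- floor(ys)
    x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
    wx <- xs - x0; wy <- ys - y0
    i00 <- (y0 + 1) + x0 * H
    i01 <- (y0 + 1) + x1 * H
    i10 <- (y1 + 1) + x0 * H
    i11 <- (y1 + 1) + x1 * H
    out <- array(0, dim = c(H, W, C))
    for (c in seq_len(C)) {
      ch <- img[, , c]
      v <- (1 - wy) * ((1 - wx) * ch[i00] + wx * ch[i01]) +
        wy * ((1 - wx) * ch[i10] + wx * ch[i11])
      out[, , c] <- matrix(v, H, W)
    }
  }
  if (two_d) out <- out[, , 1L]
  image_array(unclass(out), range = rng)
}

#' Create a batch stream over a split subset
#'
#' Train mode resizes, draws fresh augmentation parameters per image per
#' epoch, applies the affine transform, then normalizes; eval mode resizes
#' and normalizes only, visiting each image exactly once per epoch in a
#' fixed order. Labels are one-hot in sorted class-name order.
#'
#' @param manifest A `split_manifest` (from [split_dataset()]) or tibble
#'   with `subset`, `class`, `file` columns.
#' @param subset Which subset to stream (`"train"`, `"val"`, `"test"`).
#' @param mode `"train"` (augment + shuffle) or `"eval"` (neither).
#' @param batch_size Images per batch.
#' @param target_size Square side images are resized to.
#' @param seed Integer seed; streams with equal seeds emit identical batches.
#' @param root Root of the copied split tree; defaults to the manifest's
#'   `target` attribute.
#' @param ranges [augment_ranges()] used in train mode.
#' @return A `batch_stream`: environment with `next_batch()` (returns
#'   `list(x = B x H x W x 3 array, y = B x K one-hot matrix, paths)`),
#'   `reset()`, and fields `n`, `n_batches`, `classes`.
#' @export
make_stream <- function(manifest, subset = "train",
                        mode = c("train", "eval"),
                        batch_size = 16, target_size = 64, seed = 42L,
                        root = attr(manifest, "target"),
                        ranges = augment_ranges()) {
  mode <- match.arg(mode)
  rows <- manifest[manifest$subset == subset, , drop = FALSE]
  if (nrow(rows) == 0L) {
    abort(sprintf("Subset '%s' is empty.", subset), class = "sobelnet_error_validation")
  }
  classes <- sort(unique(manifest$class), method = "radix")
  paths <- file.path(root, rows$subset, rows$class, rows$file)
  ord <- order(rows$class, rows$file, method = "radix")
  paths <- paths[ord]
  labels <- match(rows$class[ord], classes)

  # Preload + resize once; phantoms at desk scale fit comfortably in memory.
  imgs <- lapply(paths, function(p) {
    raw <- read_image(p)
    ensure_rgb(resize_bilinear(unclass(raw), target_size, target_size))
  })

  env <- new.env(parent = emptyenv())
  env$n <- length(imgs)
  env$n_batches <- ceiling(env$n / batch_size)
  env$classes <- classes
  env$epoch <- 0L
  env$batch_in_epoch <- 0L
  env$order <- seq_len(env$n)
  env$mode <- mode
  env$seed <- as.integer(seed)

  start_epoch <- function() {
    env$epoch <- env$epoch + 1L
    env$batch_in_epoch <- 0L
    if (mode == "train") {
      env$order <- with_seed(mix_seed(env$seed, env$epoch, 1), sample(env$n))
    }
  }
  start_epoch()

  env$reset <- function() {
    env$epoch <- 0L
    start_epoch()
  }

  env$next_batch <- function() {
    if (env$batch_in_epoch >= env$n_batches) start_epoch()
    env$batch_in_epoch <- env$batch_in_epoch + 1L
    i0 <- (env$batch_in_epoch - 1L) * batch_size + 1L
    i1 <- min(env$batch_in_epoch * batch_size, env$n)
    idx <- env$order[i0:i1]
    B <- length(idx)
    x <- array(0, dim = c(B, target_size, target_size, 3L))
    y <- matrix(0, B, length(classes))
    for (b in seq_len(B)) {
      im <- imgs[[idx[b]]]
      if (mode == "train") {
        p <- with_seed(mix_seed(env$seed, env$epoch, 2, idx[b]),
          sample_params(ranges))
        im <- unclass(apply_affine(image_array(im, "raw"), p))
      }
      x[b, , , ] <- im / 127.5 - 1
      y[b, labels[idx[b]]] <- 1
    }
    colnames(y) <- classes
    list(x = x, y = y, paths = paths[idx])
  }

  class(env) <- "batch_stream"
  env
}

#' @export
print.batch_stream <- function(x, ...) {
  cat(sprintf("<batch_stream: %d images, %d batches/epoch, mode likely from creation>\n",
    x$n, x$n_batches))
  invisible(x)
}
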