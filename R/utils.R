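# Shared helpers: image containers, deterministic sub-seeding, resizing, I/O.

# Deterministically combine integers into one sub-seed < 2^31. Used so that
# per-image randomness depends only on (seed, class, index), never on the
# order in which images are generated. 69069 / 2147483563 keep every product
# exactly representable in a double, so results are identical across platforms.
mix_seed <- function(...) {
  v <- as.numeric(c(...))
  h <- 1234567891
  for (x in v) {
    h <- (h * 69069 + (x %% 2147483563) + 1) %% 2147483563
  }
  as.integer(h)
}

# Run expr with a temporary RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

#' Construct an image array
#'
#' Images are plain numeric arrays of shape height x width x channels with a
#' `"range"` attribute recording whether values live on the raw 8-bit scale
#' `[0, 255]` or the model's normalized scale `[-1, 1]`.
#'
#' @param x Numeric matrix (taken as one channel) or H x W x C array.
#' @param range `"raw"` or `"normalized"`.
#' @return The array with class `sobelnet_image` and a `range` attribute.
#' @export
image_array <- function(x, range = c("raw", "normalized")) {
  range <- match.arg(range)
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) {
    abort("`x` must be an H x W or H x W x C numeric array.", class = "sobelnet_error_validation")
  }
  attr(x, "range") <- range
  class(x) <- c("sobelnet_image", class(x))
  x
}

img_range <- function(x) attr(x, "range") %||% "raw"

assert_raw_range <- function(x, what = "image") {
  if (min(x) < -1e-8 || max(x) > 255 + 1e-8) {
    abort(sprintf("%s has values outside [0, 255]; not a raw-range image.", what),
      class = "sobelnet_error_validation")
  }
  invisible(x)
}

n_channels <- function(img) if (length(dim(img)) == 3L) dim(img)[3L] else 1L

# ITU-R BT.601 luminance; weights sum to 1 so the value range is preserved.
luminance <- function(img) {
  if (length(dim(img)) == 3L && dim(img)[3L] == 3L) {
    0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
  } else if (length(dim(img)) == 3L) {
    img[, , 1L]
  } else {
    img
  }
}

# Replicate a single-channel image to 3 identical channels (backbone input
# contract); 3-channel input passes through untouched.
ensure_rgb <- function(img) {
  if (length(dim(img)) == 2L) img <- array(img, dim = c(dim(img), 1L))
  if (dim(img)[3L] == 3L) return(img)
  array(rep(img[, , 1L], 3L), dim = c(dim(img)[1:2], 3L))
}

# Bilinear resize of an H x W x C array to out_h x out_w. Sample positions
# use the align-corners-free convention (pixel centers at i - 0.5).
resize_bilinear <- function(img, out_h, out_w) {
  two_d <- length(dim(img)) == 2L
  if (two_d) img <- array(img, dim = c(dim(img), 1L))
  H <- dim(img)[1L]; W <- dim(img)[2L]; C <- dim(img)[3L]
  if (H == out_h && W == out_w) {
    out <- img
  } else {
    sy <- H / out_h; sx <- W / out_w
    yy <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), H - 1)
    xx <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), W - 1)
    y0 <- floor(yy); x0 <- floor(xx)
    y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
    wy <- yy - y0; wx <- xx - x0
    out <- array(0, dim = c(out_h, out_w, C))
    for (c in seq_len(C)) {
      ch <- img[, , c]
      a <- ch[cbind(rep(y0 + 1, out_w), rep(x0 + 1, each = out_h))]
      b <- ch[cbind(rep(y0 + 1, out_w), rep(x1 + 1, each = out_h))]
      d <- ch[cbind(rep(y1 + 1, out_w), rep(x0 + 1, each = out_h))]
      e <- ch[cbind(rep(y1 + 1, out_w), rep(x1 + 1, each = out_h))]
      WY <- matrix(wy, out_h, out_w)
      WX <- matrix(wx, out_h, out_w, byrow = TRUE)
      out[, , c] <- (1 - WY) * ((1 - WX) * matrix(a, out_h) + WX * matrix(b, out_h)) +
        WY * ((1 - WX) * matrix(d, out_h) + WX * matrix(e, out_h))
    }
  }
  if (two_d) out[, , 1L] else out
}

#' Read an image file into a raw-range array
#'
#' PNG files are decoded with \pkg{png}; other raster formats (JPEG, TIFF)
#' are decoded with \pkg{EBImage} when available.
#'
#' @param path File path.
#' @return Raw-range [`image_array()`] (values in `[0, 255]`), 1 or 3 channels.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    x <- png::readPNG(path)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("Reading non-PNG images requires the EBImage package.",
        class = "sobelnet_error_io")
    }
    e <- EBImage::readImage(path)
    x <- aperm(array(as.numeric(e), dim = c(dim(e), 1L, 1L)[1:3]), c(2L, 1L, 3L))
  }
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[3L] == 4L) x <- x[, , 1:3, drop = FALSE] # drop alpha
  if (dim(x)[3L] == 2L) x <- x[, , 1L, drop = FALSE]
  image_array(x * 255, range = "raw")
}

#' Write a raw-range image array to disk
#'
#' @param img Raw-range array (`[0, 255]`), 1 or 3 channels.
#' @param path Destination; format chosen by extension (`.png` via \pkg{png},
#'   `.jpg`/`.jpeg` via \pkg{EBImage}).
#' @param quality JPEG quality (ignored for PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, quality = 95) {
  assert_raw_range(img)
  x <- pmin(pmax(img / 255, 0), 1)
  if (length(dim(x)) == 3L && dim(x)[3L] == 1L) x <- x[, , 1L]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(x, target = path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("Writing JPEG requires the EBImage package; use format = \"png\".",
        class = "sobelnet_error_io")
    }
    y <- if (length(dim(x)) == 2L) t(x) else aperm(x, c(2L, 1L, 3L))
    EBImage::writeImage(EBImage::Image(y, colormode = if (length(dim(x)) == 2L) "Grayscale" else "Color"),
      path, quality = quality)
  } else {
    abort(sprintf("Unsupported image extension '%s'.", ext), class = "sobelnet_error_io")
  }
  invisible(path)
}

# Simple blue-cyan-yellow-red colormap on [0,1]; returns H x W x 3.
jet_colormap <- function(m) {
  r <- pmin(pmax(1.5 - abs(4 * m - 3), 0), 1)
  g <- pmin(pmax(1.5 - abs(4 * m - 2), 0), 1)
  b <- pmin(pmax(1.5 - abs(4 * m - 1), 0), 1)
  array(c(r, g, b), dim = c(dim(m), 3L))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
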