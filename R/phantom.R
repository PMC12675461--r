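# Synthetic brain-phantom generator: two classes (tumor / healthy) rendered
# as an anti-aliased bright ellipse ("brain tissue") on a dark background,
# with the tumor class carrying exactly one smooth-edged bright disc whose
# support lies strictly inside the ellipse. Lesions strictly ADD intensity,
# so a pixel-sum threshold separates the classes perfectly at zero noise.

#' Phantom generator configuration
#'
#' All geometric quantities are fractions of the image side; all intensities
#' are on the `[0, 1]` scale (converted to 8-bit on write).
#'
#' @param image_size Pixels per side of the square image.
#' @param lesion_radius_range Length-2 fraction-of-size range for the lesion
#'   disc radius.
#' @param lesion_intensity_range Length-2 range of added lesion brightness.
#' @param brain_axes_range Length-2 range for the ellipse semi-axes
#'   (fraction of size); the two semi-axes are drawn independently.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param brightness_jitter Length-2 multiplicative brightness range, or
#'   `NULL` to disable.
#' @param channel_mode `"grayscale"`, `"rgb"`, or `"mixed"` (roughly half of
#'   the images encoded as single-channel, half as 3-channel gray-as-RGB,
#'   emulating datasets that mix grayscale and color encodings).
#' @param tissue_intensity Base brain-tissue intensity.
#' @param background_intensity Background intensity outside the ellipse.
#' @param seed Integer seed; together with the class label and image index it
#'   fully determines each image.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 64,
                           lesion_radius_range = c(0.07, 0.13),
                           lesion_intensity_range = c(0.25, 0.45),
                           brain_axes_range = c(0.28, 0.42),
                           noise_sd = 0.02,
                           brightness_jitter = c(0.85, 1.15),
                           channel_mode = c("mixed", "grayscale", "rgb"),
                           tissue_intensity = 0.4,
                           background_intensity = 0.03,
                           seed = 42L) {
  channel_mode <- match.arg(channel_mode)
  cfg <- list(
    image_size = as.integer(image_size),
    lesion_radius_range = as.numeric(lesion_radius_range),
    lesion_intensity_range = as.numeric(lesion_intensity_range),
    brain_axes_range = as.numeric(brain_axes_range),
    noise_sd = as.numeric(noise_sd),
    brightness_jitter = if (is.null(brightness_jitter)) NULL else as.numeric(brightness_jitter),
    channel_mode = channel_mode,
    tissue_intensity = tissue_intensity,
    background_intensity = background_intensity,
    seed = as.integer(seed)
  )
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || r[1L] > r[2L] || any(r < 0) || any(r > 1)) {
      abort(sprintf("`%s` must be an increasing length-2 range inside [0, 1].", nm),
        class = "sobelnet_error_validation")
    }
  }
  chk_range(cfg$lesion_radius_range, "lesion_radius_range")
  chk_range(cfg$lesion_intensity_range, "lesion_intensity_range")
  chk_range(cfg$brain_axes_range, "brain_axes_range")
  if (cfg$image_size < 8L) {
    abort("`image_size` must be at least 8.", class = "sobelnet_error_validation")
  }
  if (cfg$noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "sobelnet_error_validation")
  invisible(cfg)
}

phantom_class_id <- function(class_label) {
  switch(class_label,
    tumor = 1L,
    healthy = 2L,
    abort(sprintf("Unknown class label '%s'; expected 'tumor' or 'healthy'.", class_label),
      class = "sobelnet_error_validation")
  )
}

#' Generate one synthetic brain phantom
#'
#' Deterministic in `(cfg$seed, class_label, index)`: per-image randomness is
#' derived by hashing the triple, so generating image 17 alone yields the
#' same pixels as generating it as part of a batch.
#'
#' @param class_label `"tumor"` or `"healthy"`.
#' @param cfg A [phantom_config()].
#' @param index Non-negative image index.
#' @return Raw-range [image_array()] (8-bit-quantized values in `[0, 255]`).
#'   Tumor images carry attributes `lesion_mask` (logical H x W ground-truth
#'   disc support) and `lesion_center`/`lesion_radius` (pixels).
#' @export
generate_phantom <- function(class_label, cfg = phantom_config(), index = 0L) {
  validate_phantom_config(cfg)
  cls <- phantom_class_id(class_label)
  if (index < 0) abort("`index` must be >= 0.", class = "sobelnet_error_validation")
  n <- cfg$image_size
  with_seed(mix_seed(cfg$seed, cls, index), {
    a <- runif(1, cfg$brain_axes_range[1L], cfg$brain_axes_range[2L]) * n
    b <- runif(1, cfg$brain_axes_range[1L], cfg$brain_axes_range[2L]) * n
    cx <- (n - 1) / 2 + runif(1, -0.05, 0.05) * n
    cy <- (n - 1) / 2 + runif(1, -0.05, 0.05) * n

    xs <- matrix(rep(0:(n - 1), each = n), n, n)  # column coordinate
    ys <- matrix(rep(0:(n - 1), times = n), n, n) # row coordinate
    rho <- sqrt(((xs - cx) / b)^2 + ((ys - cy) / a)^2)
    # anti-aliased ellipse edge: ~1.5 px transition band
    edge_w <- 1.5 / min(a, b)
    tissue_frac <- clamp01((1 - rho) / edge_w)
    img <- cfg$background_intensity +
      (cfg$tissue_intensity - cfg$background_intensity) * tissue_frac

    mask <- NULL; center <- NULL; r <- NULL
    if (cls == 1L) {
      r <- runif(1, cfg$lesion_radius_range[1L], cfg$lesion_radius_range[2L]) * n
      amp <- runif(1, cfg$lesion_intensity_range[1L], cfg$lesion_intensity_range[2L])
      # lesion center uniform in the ellipse shrunk so the disc (+2 px
      # anti-aliasing margin) stays strictly inside the tissue region
      repeat {
        u <- runif(1, -1, 1); v <- runif(1, -1, 1)
        if (u * u + v * v <= 1) break
      }
      margin <- r + 2
      lx <- cx + u * max(b - margin, 0)
      ly <- cy + v * max(a - margin, 0)
      d <- sqrt((xs - lx)^2 + (ys - ly)^2)
      ramp_w <- max(1, 0.25 * r)
      add <- amp * clamp01((r - d) / ramp_w) # smooth-edged disc, support d < r
      img <- img + add
      mask <- d < r
      center <- c(x = lx, y = ly)
    }

    if (!is.null(cfg$brightness_jitter)) {
      img <- img * runif(1, cfg$brightness_jitter[1L], cfg$brightness_jitter[2L])
    }
    if (cfg$noise_sd > 0) {
      img <- img + matrix(rnorm(n * n, 0, cfg$noise_sd), n, n)
    }
    img <- clamp01(img)

    channels <- switch(cfg$channel_mode,
      grayscale = 1L,
      rgb = 3L,
      mixed = if (runif(1) < 0.5) 1L else 3L
    )
    raw <- round(img * 255)
    out <- if (channels == 3L) array(rep(raw, 3L), dim = c(n, n, 3L)) else array(raw, dim = c(n, n, 1L))
    out <- image_array(out, range = "raw")
    if (!is.null(mask)) {
      attr(out, "lesion_mask") <- mask
      attr(out, "lesion_center") <- center
      attr(out, "lesion_radius") <- r
    }
    out
  })
}

#' Generate an on-disk two-class phantom dataset
#'
#' Writes `<out_dir>/<class>/<class>_<index>.<ext>` and a tab-separated
#' manifest `manifest.tsv` (columns `path`, `class`).
#'
#' @param n_tumor,n_healthy Number of images per class.
#' @param out_dir Output directory (created if missing).
#' @param cfg A [phantom_config()].
#' @param format `"jpeg"` (default, 8-bit lossy) or `"png"` (lossless, for
#'   bit-exact comparisons).
#' @return A `dataset_manifest`: tibble with columns `path`, `class`, plus
#'   attributes `root` and `counts`.
#' @export
generate_dataset <- function(n_tumor, n_healthy, out_dir, cfg = phantom_config(),
                             format = c("jpeg", "png")) {
  format <- match.arg(format)
  if (n_tumor < 0 || n_healthy < 0) {
    abort("Counts must be >= 0.", class = "sobelnet_error_validation")
  }
  ext <- if (format == "jpeg") "jpg" else "png"
  classes <- c(tumor = n_tumor, healthy = n_healthy)
  rows <- vector("list", sum(classes))
  pos <- 0L
  for (cl in names(classes)) {
    dir <- file.path(out_dir, cl)
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) {
      abort(sprintf("Cannot create output directory '%s'.", dir), class = "sobelnet_error_io")
    }
    nc <- classes[[cl]]
    if (nc == 0L) next
    width <- max(4L, nchar(as.character(nc - 1L)))
    for (i in seq_len(nc) - 1L) {
      img <- generate_phantom(cl, cfg, i)
      fname <- sprintf("%s_%0*d.%s", cl, width, i, ext)
      path <- file.path(dir, fname)
      write_image(img, path)
      pos <- pos + 1L
      rows[[pos]] <- tibble(path = file.path(cl, fname), class = cl)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0L) manifest <- tibble(path = character(), class = character())
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  structure(manifest,
    root = normalizePath(out_dir),
    counts = classes,
    class = c("dataset_manifest", class(manifest)))
}

#' @export
print.dataset_manifest <- function(x, ...) {
  counts <- attr(x, "counts")
  cat("Phantom dataset at", attr(x, "root"), "\n")
  cat(sprintf("  %s: %d images\n", names(counts), counts), sep = "")
  invisible(x)
}
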