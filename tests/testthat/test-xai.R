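test_that("vanilla saliency of a linear model is exactly |w|", {
  W1 <- withr::with_seed(1, array(rnorm(6 * 6 * 3), c(6, 6, 3)))
  W2 <- withr::with_seed(2, array(rnorm(6 * 6 * 3), c(6, 6, 3)))
  lm <- linear_pixel_model(list(W1, W2))
  img <- withr::with_seed(3, array(rnorm(6 * 6 * 3), c(6, 6, 3)))
  sal <- vanilla_saliency(lm, img, 1)
  expect_equal(unclass(sal)[1:6, 1:6], apply(abs(W1), c(1, 2), max),
    ignore_attr = TRUE)
  expect_true(all(sal >= 0))
  # constant (all-zero-weight) model yields an all-zero map
  z <- vanilla_saliency(linear_pixel_model(list(W1 * 0, W2)), img, 1)
  expect_equal(max(abs(z)), 0)
})

test_that("saliency on the network model is nonnegative and deterministic", {
  m <- tiny_model(conv_filters = 4, dense_units = 8)
  x <- withr::with_seed(4, array(rnorm(16 * 16 * 3, sd = 0.3), c(16, 16, 3)))
  s1 <- vanilla_saliency(m, x, "tumor")
  s2 <- vanilla_saliency(m, x, "tumor")
  expect_identical(unclass(s1), unclass(s2))
  expect_true(all(s1 >= 0))
  expect_equal(dim(s1), c(16L, 16L))
  expect_error(vanilla_saliency(m, x, "glioma"), class = "sobelnet_error_validation")
})

test_that("grad-cam and grad-cam++ reduce to relu(A) on the single-map model", {
  A <- withr::with_seed(5, array(abs(rnorm(4 * 4 * 3)), c(4, 4, 3)))
  A[, , 2] <- A[, , 2] - 0.5 # give the scored map some negative entries
  mm <- analytic_map_model(A, map_index = c(2L, 1L))
  img <- array(0, c(8, 8, 3))
  g1 <- grad_cam(mm, img, 1)
  g2 <- grad_cam_pp(mm, img, 1)
  expected <- sobelnet:::minmax_norm(resize_bilinear(pmax(A[, , 2], 0), 8, 8))
  expect_equal(unclass(g1), expected, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(unclass(g2), expected, ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(all(g1 >= 0 & g1 <= 1))
  expect_true(all(g2 >= 0 & g2 <= 1))
})

test_that("grad-cam on the network is normalized, sized, and layer-checked", {
  m <- tiny_model(conv_filters = 4, dense_units = 8)
  x <- withr::with_seed(6, array(rnorm(16 * 16 * 3, sd = 0.3), c(16, 16, 3)))
  g <- grad_cam(m, x, "tumor")
  expect_equal(dim(g), c(16L, 16L))
  expect_true(all(g >= 0 & g <= 1))
  expect_error(grad_cam(m, x, "tumor", layer = "mixed10"),
    class = "sobelnet_error_validation")
})

test_that("LIME recovers the single causal segment against the WLS oracle", {
  # 12 x 12 image over a 2 x 3 grid of segments; the model returns 1 iff
  # segment 5 is present
  segs <- matrix(0L, 12, 12)
  segs[1:6, 1:4] <- 1L; segs[1:6, 5:8] <- 2L; segs[1:6, 9:12] <- 3L
  segs[7:12, 1:4] <- 4L; segs[7:12, 5:8] <- 5L; segs[7:12, 9:12] <- 6L
  img <- matrix(seq(0, 1, length.out = 144), 12, 12)
  baseline <- -1
  model_fn <- function(imgs) {
    vapply(imgs, function(im) as.numeric(any(im[7:12, 5:8] != baseline)), numeric(1))
  }
  masks <- as.matrix(expand.grid(rep(list(0:1), 6))) # exhaustive design
  ex <- lime_explain(model_fn, img, class = 1, segments = segs,
    perturbations = masks, k = 2, baseline = baseline, ridge = 1e-10)
  w <- ex$weights$weight
  expect_equal(which.max(w), 5L)
  expect_gt(w[5], max(w[-5]) + 0.5)
  expect_equal(ex$top_k[1], 5L)

  # closed-form weighted least squares oracle on the same design
  y <- masks[, 5]
  frac <- rowSums(masks) / 6
  kw <- exp(-((1 - sqrt(frac))^2) / 0.25^2)
  fit <- stats::lm.wfit(cbind(1, masks), y, kw)
  expect_equal(w, unname(fit$coefficients[-1]), tolerance = 1e-6)
})

test_that("LIME is seed-deterministic and silent on constant models", {
  img <- withr::with_seed(7, matrix(runif(256), 16, 16))
  const_fn <- function(imgs) rep(0.42, length(imgs))
  e1 <- lime_explain(const_fn, img, class = 1, n_segments = 8, n_samples = 40, seed = 3)
  e2 <- lime_explain(const_fn, img, class = 1, n_segments = 8, n_samples = 40, seed = 3)
  expect_identical(e1$weights, e2$weights)
  expect_lt(max(abs(e1$weights$weight)), 1e-8)
  expect_error(lime_explain(const_fn, img, class = 1, n_segments = 1),
    class = "sobelnet_error_validation")
})

test_that("superpixels partition the image into the requested scale", {
  img <- withr::with_seed(8, matrix(runif(400), 20, 20))
  segs <- slic_superpixels(img, n_segments = 9)
  expect_equal(dim(segs), c(20L, 20L))
  m <- max(segs)
  expect_true(m >= 2 && m <= 9)
  expect_setequal(unique(as.vector(segs)), seq_len(m))
})

test_that("LIME ranking correlates with single-segment occlusion", {
  cfg <- phantom_config(image_size = 32, channel_mode = "grayscale",
    noise_sd = 0, seed = 31)
  img <- unclass(generate_phantom("tumor", cfg, 2))[, , 1] / 255
  # intensity-driven probability model: brighter image -> more "tumor"
  prob_fn <- function(imgs) {
    vapply(imgs, function(im) stats::plogis(40 * (mean(im) - 0.2)), numeric(1))
  }
  segs <- slic_superpixels(img, n_segments = 12)
  ex <- lime_explain(prob_fn, img, class = 1, segments = segs,
    n_samples = 300, seed = 5, baseline = 0)
  p0 <- prob_fn(list(img))
  m <- max(segs)
  drops <- vapply(seq_len(m), function(j) {
    occ <- img; occ[segs == j] <- 0
    p0 - prob_fn(list(occ))
  }, numeric(1))
  expect_gt(stats::cor(ex$weights$weight, drops, method = "spearman"), 0)
})

test_that("overlays blend the heatmap onto the grayscale base as documented", {
  img <- image_array(matrix(runif(64, 0, 255), 8, 8), "raw")
  map <- withr::with_seed(9, matrix(runif(64), 8, 8))
  f <- withr::local_tempfile(fileext = ".png")
  render_overlay(img, map, f, alpha = 0.45)
  out <- png::readPNG(f)
  expect_equal(dim(out)[1:2], c(8L, 8L))
  base <- sobelnet:::luminance(unclass(img)) / 255
  hm <- sobelnet:::jet_colormap(map)
  for (i in withr::with_seed(10, sample(64, 5))) {
    for (c in 1:3) {
      expected <- 0.55 * base[i] + 0.45 * hm[, , c][i]
      # exact up to 8-bit quantization of the written PNG
      expect_lt(abs(out[, , c][i] - min(max(expected, 0), 1)), 1 / 255)
    }
  }
  # an all-zero map leaves only the attenuated base in the red channel
  f2 <- withr::local_tempfile(fileext = ".png")
  render_overlay(img, map * 0, f2)
  out2 <- png::readPNG(f2)
  expect_lt(max(abs(out2[, , 1] - 0.55 * base)), 1 / 255)
})
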