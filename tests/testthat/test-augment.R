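test_that("pixel normalization maps [0, 255] linearly onto [-1, 1]", {
  img <- image_array(matrix(c(0, 127.5, 255, 51), 2, 2), "raw")
  out <- preprocess_pixels(img)
  expect_equal(as.vector(unclass(out))[1:3], c(-1, 0, 1))
  expect_equal(attr(out, "range"), "normalized")
  # linear: order and ratios of intensity differences preserved
  expect_equal(unclass(out)[2, 1, 1] - unclass(out)[1, 1, 1], 127.5 / 127.5)
  expect_error(preprocess_pixels(image_array(matrix(300, 2, 2), "raw")),
    class = "sobelnet_error_validation")
})

test_that("identity parameters return the image exactly; flip is an involution", {
  img <- image_array(matrix(runif(64, 0, 255), 8, 8), "raw")
  expect_identical(unclass(apply_affine(img, identity_params())), unclass(img))

  p_flip <- identity_params(); p_flip$flip <- TRUE
  once <- apply_affine(img, p_flip)
  twice <- apply_affine(once, p_flip)
  expect_identical(unclass(twice), unclass(img))
  expect_false(identical(unclass(once), unclass(img)))
})

test_that("a pure integer shift relocates a delta by the exact pixel offset", {
  W <- 32L
  m <- matrix(0, W, W); m[16, 10] <- 255
  img <- image_array(m, "raw")
  p <- identity_params(); p$shift_x <- 4 / W # 4 pixels right
  out <- unclass(apply_affine(img, p))[, , 1]
  hit <- which(out == max(out), arr.ind = TRUE)
  expect_equal(unname(hit[1, ]), c(16, 14))
  p2 <- identity_params(); p2$shift_y <- -3 / W # 3 pixels up
  out2 <- unclass(apply_affine(img, p2))[, , 1]
  hit2 <- which(out2 == max(out2), arr.ind = TRUE)
  expect_equal(unname(hit2[1, ]), c(13, 10))
})

test_that("rotation round trip is accurate in the interior of smooth images", {
  n <- 48
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- t(xs)
  smooth <- exp(-((xs - 20)^2 + (ys - 30)^2) / 120) # [0, 1] Gaussian blob
  img <- image_array(smooth * 255, "raw")
  p <- identity_params(); p$rotation_deg <- 17
  q <- identity_params(); q$rotation_deg <- -17
  back <- unclass(apply_affine(apply_affine(img, p), q))[, , 1] / 255
  interior <- 13:36
  expect_lt(max(abs(back[interior, interior] - smooth[interior, interior])), 0.1)
})

test_that("sampled parameters respect every configured range", {
  ranges <- augment_ranges()
  draws <- withr::with_seed(99, replicate(10000, sample_params(ranges), simplify = FALSE))
  rot <- vapply(draws, `[[`, numeric(1), "rotation_deg")
  zoom <- vapply(draws, `[[`, numeric(1), "zoom")
  shear <- vapply(draws, `[[`, numeric(1), "shear")
  flips <- vapply(draws, `[[`, logical(1), "flip")
  expect_true(all(rot >= -20 & rot <= 20))
  expect_true(all(zoom >= 0.8 & zoom <= 1.2))
  expect_true(all(shear >= -0.2 & shear <= 0.2))
  # Bernoulli(1/2) flip: 3-sigma binomial band at n = 10,000
  expect_lt(abs(mean(flips) - 0.5), 3 * sqrt(0.25 / 10000))
  # seeded draws replay identically
  expect_identical(withr::with_seed(7, sample_params(ranges)),
    withr::with_seed(7, sample_params(ranges)))
})

test_that("zoom must be positive", {
  img <- image_array(matrix(1, 8, 8), "raw")
  p <- identity_params(); p$zoom <- 0
  expect_error(apply_affine(img, p), class = "sobelnet_error_validation")
})

test_that("eval streams cover each image exactly once with one-hot labels", {
  src <- withr::local_tempdir(); tgt <- withr::local_tempdir()
  make_file_tree(src, c(tumor = 8, healthy = 6), image_size = 16)
  m <- split_dataset(split_spec(c(0.5, 0.25, 0.25), source = src, target = tgt))
  st <- make_stream(m, "train", "eval", batch_size = 3, target_size = 16)
  n <- sum(m$subset == "train")
  expect_equal(st$n_batches, ceiling(n / 3))
  seen <- character(); labsum <- 0
  for (i in seq_len(st$n_batches)) {
    b <- st$next_batch()
    expect_true(all(rowSums(b$y) == 1))
    expect_true(all(b$y %in% c(0, 1)))
    expect_true(all(b$x >= -1 - 1e-12 & b$x <= 1 + 1e-12))
    seen <- c(seen, b$paths)
    labsum <- labsum + sum(b$y)
  }
  expect_length(unique(seen), n)
  expect_equal(labsum, n)
})

test_that("train streams with equal seeds emit identical augmented batches", {
  src <- withr::local_tempdir(); tgt <- withr::local_tempdir()
  make_file_tree(src, c(tumor = 6, healthy = 6), image_size = 16)
  m <- split_dataset(split_spec(c(1, 0, 0), source = src, target = tgt))
  s1 <- make_stream(m, "train", "train", batch_size = 4, target_size = 16, seed = 5)
  s2 <- make_stream(m, "train", "train", batch_size = 4, target_size = 16, seed = 5)
  for (i in 1:4) { # crosses an epoch boundary
    b1 <- s1$next_batch(); b2 <- s2$next_batch()
    expect_identical(b1$x, b2$x)
    expect_identical(b1$y, b2$y)
  }
  # augmentation actually perturbs pixels relative to an eval stream
  e <- make_stream(m, "train", "eval", batch_size = 4, target_size = 16)
  s1$reset(); e$reset()
  expect_false(identical(s1$next_batch()$x, e$next_batch()$x))
})
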