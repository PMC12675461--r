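test_that("softmax outputs are valid distributions and fusion has the right width", {
  m <- tiny_model(conv_filters = 8)
  for (i in 1:5) {
    x <- withr::with_seed(i, array(rnorm(16 * 16 * 3), c(16, 16, 3)))
    fw <- sobelnet:::fwd_image(m, x)
    expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
    expect_true(all(fw$probs >= 0))
    expect_length(fw$cache$f, 64 + 8) # backbone channels + edge filters
  }
})

test_that("fine_tune_at freezes exactly the expected parameters", {
  m <- tiny_model(fine_tune_at = 3)
  # hand count of the tiny backbone: conv1 3*3*3*16+16, conv2 3*3*16*32+32,
  # conv3 3*3*32*64+64
  backbone <- (9 * 3 * 16 + 16) + (9 * 16 * 32 + 32) + (9 * 32 * 64 + 64)
  sobel <- 2 * 9
  expect_equal(n_parameters(m, trainable_only = TRUE),
    n_parameters(m) - backbone - sobel)
  expect_true(all(c("se_W1", "edge_W", "fc1_W", "out_W") %in% trainable_names(m)))
  expect_false(any(c("conv1_W", "conv2_b", "sobel_x") %in% trainable_names(m)))
})

test_that("frozen tensors are bit-identical after training", {
  b <- phantom_batch(8, image_size = 16)
  tr <- stub_stream(b$x, b$y, batch_size = 8)
  m <- tiny_model(fine_tune_at = 3, dense_units = 16, conv_filters = 4)
  before <- m$params[c("conv1_W", "conv2_W", "conv3_W", "sobel_x", "sobel_y")]
  m2 <- train_model(m, tr, tr, epochs = 2)
  expect_identical(m2$params[names(before)], before)
  # unfrozen head did move
  expect_false(identical(m2$params$out_W, m$params$out_W))
})

test_that("learning-rate plateau halves after the configured stagnation", {
  st <- reduce_lr_state(lr = 0.1, factor = 0.5, patience = 1, min_lr = 1e-3)
  # constant (never-improving after the first epoch) monitor
  st <- reduce_lr_step(st, 1.0) # first value becomes best
  expect_equal(st$lr, 0.1)
  st <- reduce_lr_step(st, 1.0) # second stagnant epoch triggers the cut
  expect_equal(st$lr, 0.05)
  for (i in 1:20) st <- reduce_lr_step(st, 1.0)
  expect_gte(st$lr, 1e-3) # floor respected
  expect_equal(st$lr, 1e-3)
})

test_that("early stopping fires patience epochs after the last improvement", {
  p <- 3L
  st <- early_stopping_state(patience = p, restore_best = TRUE)
  st <- early_stopping_step(st, 0.5, 1) # improves at epoch 1 only
  epoch <- 1L
  while (!st$stop) {
    epoch <- epoch + 1L
    st <- early_stopping_step(st, 0.7, epoch)
  }
  expect_equal(epoch, 1L + p)
  expect_equal(st$best_epoch, 1L)
})

test_that("training restores best weights and records history", {
  b <- phantom_batch(10, image_size = 16)
  tr <- stub_stream(b$x, b$y, batch_size = 10)
  m <- tiny_model(dense_units = 16, conv_filters = 4, lr = 1e-3)
  m2 <- train_model(m, tr, tr, epochs = 3)
  h <- m2$history
  expect_s3_class(h, "sobelnet_history")
  expect_equal(nrow(h), 3)
  expect_named(h, c("epoch", "loss", "accuracy", "val_loss", "val_accuracy", "lr"))
  expect_true(all(diff(h$lr) <= 0)) # lr trace is non-increasing
  g <- glance(h)
  expect_equal(g$epochs_run, 3)
})

test_that("seeded training is exactly reproducible", {
  b <- phantom_batch(8, image_size = 16)
  tr1 <- stub_stream(b$x, b$y, batch_size = 8)
  tr2 <- stub_stream(b$x, b$y, batch_size = 8)
  m1 <- train_model(tiny_model(dropout_rate = 0.3), tr1, tr1, epochs = 2)
  m2 <- train_model(tiny_model(dropout_rate = 0.3), tr2, tr2, epochs = 2)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("non-finite losses abort with a diagnostic", {
  b <- phantom_batch(4, image_size = 16)
  b$x[1, 1, 1, 1] <- NaN
  tr <- stub_stream(b$x, b$y, batch_size = 4)
  m <- tiny_model(dense_units = 8, conv_filters = 4)
  expect_error(train_model(m, tr, tr, epochs = 1),
    class = "sobelnet_error_numeric")
})

test_that("prediction returns calibrated rows and argmax labels", {
  m <- tiny_model(conv_filters = 4, dense_units = 8)
  b <- phantom_batch(3, image_size = 16)
  out <- predict(m, b$x)
  expect_equal(nrow(out), 6)
  probs <- as.matrix(out[, c(".prob_healthy", ".prob_tumor")])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  # independent argmax oracle
  oracle <- c("healthy", "tumor")[apply(probs, 1, which.max)]
  expect_equal(as.character(out$.pred_class), oracle)

  # zeroed head: exactly uniform probabilities, ties resolve to class 1
  m$params$out_W[] <- 0; m$params$out_b[] <- 0
  u <- predict(m, b$x[1, , , , drop = FALSE])
  expect_equal(unname(as.matrix(u[, 1:2])[1, ]), c(0.5, 0.5))
  expect_equal(as.character(u$.pred_class), "healthy")
})

test_that("weights round-trip through serialization", {
  m <- tiny_model()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model_weights(m, f)
  m2 <- tiny_model(seed = 99) # different init
  expect_false(identical(m2$params, m$params))
  m2 <- load_model_weights(m2, f)
  expect_identical(m2$params, m$params)
  # architecture mismatch (different edge filter count) is rejected
  expect_error(load_model_weights(tiny_model(conv_filters = 3), f),
    class = "sobelnet_error_validation")
})

test_that("only the tiny backbone is accepted", {
  expect_error(model_config(backbone = "full"), class = "sobelnet_error_validation")
  expect_error(model_config(img_size = 30), class = "sobelnet_error_validation")
  expect_error(model_config(dropout_rate = 1), class = "sobelnet_error_validation")
})
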