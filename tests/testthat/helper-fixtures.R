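# Shared fixtures: brute-force oracles and tiny in-memory streams.

# Brute-force 3x3 cross-correlation with zero or replicate padding; the
# independent oracle for every convolution in the package.
brute_conv3 <- function(x, K, b = NULL, pad = "zero") {
  H <- dim(x)[1L]; W <- dim(x)[2L]
  Cin <- if (length(dim(x)) == 3L) dim(x)[3L] else 1L
  if (length(dim(x)) == 2L) x <- array(x, dim = c(H, W, 1L))
  Cout <- dim(K)[4L]
  out <- array(0, dim = c(H, W, Cout))
  for (o in seq_len(Cout)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        s <- if (is.null(b)) 0 else b[o]
        for (u in 1:3) {
          for (v in 1:3) {
            ii <- i + u - 2L; jj <- j + v - 2L
            val <- if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
              x[ii, jj, ]
            } else if (pad == "replicate") {
              x[min(max(ii, 1L), H), min(max(jj, 1L), W), ]
            } else {
              rep(0, Cin)
            }
            s <- s + sum(K[u, v, , o] * val)
          }
        }
        out[i, j, o] <- s
      }
    }
  }
  out
}

# Pairwise-counting AUC oracle (ties count 1/2).
brute_auc <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (n in neg) total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Deterministic in-memory stream (duck-typed like make_stream output) for
# exercising the training loop without touching disk.
stub_stream <- function(x, y, batch_size = nrow(y)) {
  env <- new.env(parent = emptyenv())
  env$n <- dim(x)[1L]
  env$n_batches <- ceiling(env$n / batch_size)
  env$classes <- colnames(y)
  env$i <- 0L
  env$reset <- function() env$i <- 0L
  env$next_batch <- function() {
    if (env$i >= env$n_batches) env$i <- 0L
    env$i <- env$i + 1L
    idx <- ((env$i - 1L) * batch_size + 1L):min(env$i * batch_size, env$n)
    list(x = x[idx, , , , drop = FALSE], y = y[idx, , drop = FALSE])
  }
  class(env) <- "batch_stream"
  env
}

# Small labelled phantom batch as normalized arrays + one-hot labels.
phantom_batch <- function(n_per_class, image_size = 16, seed = 11,
                          noise_sd = 0.02) {
  cfg <- phantom_config(image_size = image_size, noise_sd = noise_sd,
    channel_mode = "grayscale", seed = seed)
  n <- 2L * n_per_class
  x <- array(0, dim = c(n, image_size, image_size, 3L))
  y <- matrix(0, n, 2L, dimnames = list(NULL, c("healthy", "tumor")))
  for (i in seq_len(n_per_class)) {
    tum <- generate_phantom("tumor", cfg, i - 1L)
    hea <- generate_phantom("healthy", cfg, i - 1L)
    x[i, , , ] <- sobelnet:::ensure_rgb(unclass(tum)) / 127.5 - 1
    x[n_per_class + i, , , ] <- sobelnet:::ensure_rgb(unclass(hea)) / 127.5 - 1
    y[i, "tumor"] <- 1
    y[n_per_class + i, "healthy"] <- 1
  }
  list(x = x, y = y, cfg = cfg)
}

tiny_model <- function(img_size = 16, seed = 5, dense_units = 32,
                       conv_filters = 8, dropout_rate = 0, lr = 1e-3, ...) {
  build_model(
    model_config(img_size = img_size, dense_units = dense_units,
      dropout_rate = dropout_rate, learning_rate = lr, seed = seed, ...),
    edge_config(conv_filters = conv_filters),
    se_config(),
    classes = c("healthy", "tumor")
  )
}

# Class-folder tree of trivially small PNGs for split tests.
make_file_tree <- function(root, counts, image_size = 8, seed = 3) {
  cfg <- phantom_config(image_size = image_size, channel_mode = "grayscale",
    seed = seed)
  generate_dataset(counts[["tumor"]], counts[["healthy"]], root, cfg,
    format = "png")
}
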