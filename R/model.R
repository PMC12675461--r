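# Dual-branch classifier. Semantic branch: three conv(3x3)+ReLU stages
# (16/32/64 filters, max-pooled after the first two), squeeze-and-excitation
# recalibration of the final 64-channel feature map, global average pooling.
# Edge branch: luminance -> fixed Sobel gradients -> magnitude -> one
# learnable conv + ReLU -> global average pooling. The pooled vectors are
# concatenated and classified by dense(units)+ReLU -> dropout -> dense(K)
# -> softmax, trained with categorical cross-entropy and Adam. Backward is
# exact hand-derived backpropagation through both branches (verified against
# finite differences in the test suite), which also provides the input and
# feature-map gradients the attribution methods need.

.lum_weights <- c(0.299, 0.587, 0.114)

#' Model configuration
#'
#' @param img_size Square input side; must be divisible by 4 (two pooling
#'   stages). Default 64, the desk-test scale.
#' @param backbone Only `"tiny"` (3 conv stages, 16/32/64 filters) is
#'   implemented.
#' @param pretrained_weights Optional path to a weights file saved by
#'   [save_model_weights()]; `NULL` for seeded random initialization.
#' @param fine_tune_at 0-based backbone layer index at which fine-tuning
#'   starts; layers below it are frozen. 0 trains everything; 3 freezes the
#'   whole backbone.
#' @param dense_units Width of the fused dense layer (default 1024).
#' @param dropout_rate Dropout fraction after the dense layer.
#' @param num_classes Number of output classes (2).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs,batch_size,steps_per_epoch Training loop sizes
#'   (`steps_per_epoch = NULL` means one full pass).
#' @param early_stop List: `monitor` (only `"val_loss"`), `patience`,
#'   `restore_best`.
#' @param lr_plateau List: `monitor`, `factor`, `patience`, `min_lr`.
#' @param seed Seed fixing initialization, shuffling, and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(img_size = 64L, backbone = "tiny",
                         pretrained_weights = NULL,
                         fine_tune_at = 0L, dense_units = 1024L,
                         dropout_rate = 0.5, num_classes = 2L,
                         learning_rate = 1e-4, epochs = 15L, batch_size = 16L,
                         steps_per_epoch = NULL,
                         early_stop = list(monitor = "val_loss", patience = 5L,
                           restore_best = TRUE),
                         lr_plateau = list(monitor = "val_loss", factor = 0.5,
                           patience = 3L, min_lr = 1e-6),
                         seed = 42L) {
  if (!identical(backbone, "tiny")) {
    abort(paste0("Only backbone = \"tiny\" is implemented in this package; ",
      "large pretrained backbones require an external deep-learning runtime."),
      class = "sobelnet_error_validation")
  }
  if (img_size %% 4L != 0L || img_size < 12L) {
    abort("`img_size` must be a multiple of 4 and >= 12.", class = "sobelnet_error_validation")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("`dropout_rate` must lie in [0, 1).", class = "sobelnet_error_validation")
  }
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.", class = "sobelnet_error_validation")
  if (fine_tune_at < 0L || fine_tune_at > 3L) {
    abort("`fine_tune_at` must be within the backbone depth (0..3).",
      class = "sobelnet_error_validation")
  }
  structure(list(img_size = as.integer(img_size), backbone = backbone,
    pretrained_weights = pretrained_weights,
    fine_tune_at = as.integer(fine_tune_at),
    dense_units = as.integer(dense_units), dropout_rate = dropout_rate,
    num_classes = as.integer(num_classes), learning_rate = learning_rate,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    steps_per_epoch = steps_per_epoch,
    early_stop = early_stop, lr_plateau = lr_plateau,
    seed = as.integer(seed)), class = "model_config")
}

backbone_filters <- c(16L, 32L, 64L)

#' Assemble the dual-branch model
#'
#' @param cfg A [model_config()].
#' @param edge_cfg An [edge_config()].
#' @param se_cfg An [se_config()]; its channel count is set to the backbone
#'   output width (64).
#' @param classes Character vector of class names (sorted internally; the
#'   one-hot/label order used everywhere).
#' @return A `sobelnet_model`.
#' @export
build_model <- function(cfg = model_config(), edge_cfg = edge_config(),
                        se_cfg = se_config(), classes = c("healthy", "tumor")) {
  se_cfg <- se_config(ratio = se_cfg$ratio, channels = backbone_filters[3L])
  ks <- sobel_kernels()
  params <- with_seed(mix_seed(cfg$seed, 101), {
    fused <- backbone_filters[3L] + edge_cfg$conv_filters
    list(
      conv1_W = init_conv(3L, backbone_filters[1L]), conv1_b = numeric(backbone_filters[1L]),
      conv2_W = init_conv(backbone_filters[1L], backbone_filters[2L]), conv2_b = numeric(backbone_filters[2L]),
      conv3_W = init_conv(backbone_filters[2L], backbone_filters[3L]), conv3_b = numeric(backbone_filters[3L]),
      se_W1 = init_dense(se_cfg$channels, se_cfg$bottleneck), se_b1 = numeric(se_cfg$bottleneck),
      se_W2 = init_dense(se_cfg$bottleneck, se_cfg$channels), se_b2 = numeric(se_cfg$channels),
      sobel_x = array(ks$sx, dim = c(3L, 3L, 1L, 1L)),
      sobel_y = array(ks$sy, dim = c(3L, 3L, 1L, 1L)),
      edge_W = init_conv(1L, edge_cfg$conv_filters), edge_b = numeric(edge_cfg$conv_filters),
      fc1_W = init_dense(fused, cfg$dense_units), fc1_b = numeric(cfg$dense_units),
      out_W = init_dense(cfg$dense_units, cfg$num_classes), out_b = numeric(cfg$num_classes)
    )
  })
  model <- structure(list(cfg = cfg, edge_cfg = edge_cfg, se_cfg = se_cfg,
    params = params, classes = sort(as.character(classes), method = "radix"),
    history = NULL), class = "sobelnet_model")
  if (!is.null(cfg$pretrained_weights)) {
    model <- load_model_weights(model, cfg$pretrained_weights)
  }
  model
}

#' Names of trainable parameter tensors
#'
#' Backbone layers below `fine_tune_at` are frozen; the Sobel kernels are
#' trainable only when `edge_cfg$trainable_filters` is `TRUE`; the SE block,
#' edge convolution, and head always train.
#'
#' @param model A `sobelnet_model`.
#' @return Character vector of parameter names updated by the optimizer.
#' @export
trainable_names <- function(model) {
  nms <- names(model$params)
  frozen <- character()
  layer_names <- list(c("conv1_W", "conv1_b"), c("conv2_W", "conv2_b"), c("conv3_W", "conv3_b"))
  for (i in seq_along(layer_names)) {
    if ((i - 1L) < model$cfg$fine_tune_at) frozen <- c(frozen, layer_names[[i]])
  }
  if (!model$edge_cfg$trainable_filters) frozen <- c(frozen, "sobel_x", "sobel_y")
  setdiff(nms, frozen)
}

#' Parameter counts
#' @param model A `sobelnet_model`.
#' @param trainable_only Count only trainable tensors?
#' @return Integer total number of scalar parameters.
#' @export
n_parameters <- function(model, trainable_only = FALSE) {
  nms <- if (trainable_only) trainable_names(model) else names(model$params)
  sum(vapply(model$params[nms], length, integer(1)))
}

#' Save / load model weights
#'
#' Weights are serialized with [saveRDS()] (the package's native format).
#'
#' @param model A `sobelnet_model`.
#' @param path File path.
#' @return `path` (save) or the model with weights replaced (load).
#' @export
save_model_weights <- function(model, path) {
  saveRDS(model$params, path)
  invisible(path)
}

#' @rdname save_model_weights
#' @export
load_model_weights <- function(model, path) {
  if (!file.exists(path)) {
    abort(sprintf("Weights file '%s' not found.", path), class = "sobelnet_error_io")
  }
  w <- readRDS(path)
  for (nm in names(model$params)) {
    if (is.null(w[[nm]]) || !identical(dim(w[[nm]]) %||% length(w[[nm]]),
        dim(model$params[[nm]]) %||% length(model$params[[nm]]))) {
      abort(sprintf("Weights file is incompatible with this architecture (tensor '%s').", nm),
        class = "sobelnet_error_validation")
    }
  }
  model$params <- w[names(model$params)]
  model
}

# ---- forward / backward ----------------------------------------------------

# x: img_size x img_size x 3 normalized array. Returns logits, probs, and a
# cache of every intermediate the backward pass needs.
fwd_image <- function(model, x, training = FALSE) {
  p <- model$params
  n <- model$cfg$img_size
  H <- n; W <- n
  xm <- matrix(x, H * W, 3L)
  c1 <- conv3_forward(xm, H, W, p$conv1_W, p$conv1_b, "zero"); a1 <- relu(c1$out)
  pl1 <- maxpool2_forward(a1, H, W); H1 <- H %/% 2L; W1 <- W %/% 2L
  c2 <- conv3_forward(pl1$out, H1, W1, p$conv2_W, p$conv2_b, "zero"); a2 <- relu(c2$out)
  pl2 <- maxpool2_forward(a2, H1, W1); H2 <- H1 %/% 2L; W2 <- W1 %/% 2L
  c3 <- conv3_forward(pl2$out, H2, W2, p$conv3_W, p$conv3_b, "zero"); A <- relu(c3$out)

  z <- colMeans(A)
  pre1 <- drop(z %*% p$se_W1) + p$se_b1; h1 <- relu(pre1)
  pre2 <- drop(h1 %*% p$se_W2) + p$se_b2; s <- sigmoid(pre2)
  f_cnn <- s * z # == colMeans of the reweighted feature map

  lum <- xm %*% .lum_weights
  gxc <- conv3_forward(lum, H, W, p$sobel_x, NULL, "replicate")
  gy <- conv3_forward(lum, H, W, p$sobel_y, NULL, "replicate")$out
  gx <- gxc$out
  G <- sqrt(gx^2 + gy^2)
  ce <- conv3_forward(G, H, W, p$edge_W, p$edge_b, "replicate"); ae <- relu(ce$out)
  f_edge <- colMeans(ae)

  f <- c(f_cnn, f_edge)
  pre_d <- drop(f %*% p$fc1_W) + p$fc1_b; d1 <- relu(pre_d)
  mask <- NULL
  d1d <- d1
  if (training && model$cfg$dropout_rate > 0) {
    keep <- 1 - model$cfg$dropout_rate
    mask <- (runif(length(d1)) < keep) / keep
    d1d <- d1 * mask
  }
  logits <- drop(d1d %*% p$out_W) + p$out_b
  m <- max(logits); e <- exp(logits - m)
  probs <- e / sum(e)

  list(logits = logits, probs = probs,
    cache = list(xm = xm, H = H, W = W, H1 = H1, W1 = W1, H2 = H2, W2 = W2,
      c1 = c1, a1 = a1, pl1 = pl1, c2 = c2, pl2 = pl2, c3 = c3, A = A,
      z = z, pre1 = pre1, h1 = h1, s = s,
      lum_patches = gxc$patches, gx = gx, gy = gy, G = G, ce = ce, ae = ae,
      f = f, pre_d = pre_d, mask = mask, d1d = d1d))
}

# dlogits: gradient of the scalar objective w.r.t. the logits. Returns
# parameter gradients, optional input gradient (H x W x 3), and the gradient
# of the objective w.r.t. the final backbone feature map A (for CAMs).
bwd_image <- function(model, cache, dlogits, need_input = FALSE,
                      need_params = TRUE) {
  p <- model$params
  ca <- cache
  g <- list()
  if (need_params) {
    g$out_W <- outer(ca$d1d, dlogits)
    g$out_b <- dlogits
  }
  dd1d <- drop(p$out_W %*% dlogits)
  dd1 <- if (!is.null(ca$mask)) dd1d * ca$mask else dd1d
  dpre_d <- dd1 * (ca$pre_d > 0)
  if (need_params) {
    g$fc1_W <- outer(ca$f, dpre_d)
    g$fc1_b <- dpre_d
  }
  df <- drop(p$fc1_W %*% dpre_d)
  C <- length(ca$z)
  dfcnn <- df[seq_len(C)]
  dfedge <- df[(C + 1L):length(df)]

  # edge branch
  nE <- nrow(ca$ae)
  dae <- matrix(dfedge / nE, nE, length(dfedge), byrow = TRUE)
  dce <- dae * (ca$ce$out > 0)
  need_edge_dx <- need_input || (need_params && model$edge_cfg$trainable_filters)
  bke <- conv3_backward(dce, ca$ce$patches, p$edge_W, ca$H, ca$W, "replicate",
    need_dx = need_edge_dx, need_dw = need_params)
  if (need_params) {
    g$edge_W <- bke$dK; g$edge_b <- bke$db
  }
  dxm_edge <- NULL
  if (need_edge_dx) {
    dG <- bke$dx
    denom <- pmax(ca$G, 1e-12)
    dgx <- dG * ca$gx / denom
    dgy <- dG * ca$gy / denom
    bx <- conv3_backward(dgx, ca$lum_patches, p$sobel_x, ca$H, ca$W, "replicate",
      need_dx = need_input, need_dw = need_params && model$edge_cfg$trainable_filters)
    by <- conv3_backward(dgy, ca$lum_patches, p$sobel_y, ca$H, ca$W, "replicate",
      need_dx = need_input, need_dw = need_params && model$edge_cfg$trainable_filters)
    if (need_params && model$edge_cfg$trainable_filters) {
      g$sobel_x <- bx$dK; g$sobel_y <- by$dK
    }
    if (need_input) {
      dlum <- bx$dx + by$dx
      dxm_edge <- dlum %*% matrix(.lum_weights, 1L, 3L)
    }
  }

  # SE block (f_cnn = s * z, with s = gate(z))
  ds <- dfcnn * ca$z
  dz <- dfcnn * ca$s
  dpre2 <- ds * ca$s * (1 - ca$s)
  if (need_params) {
    g$se_W2 <- outer(ca$h1, dpre2); g$se_b2 <- dpre2
  }
  dh1 <- drop(p$se_W2 %*% dpre2)
  dpre1 <- dh1 * (ca$pre1 > 0)
  if (need_params) {
    g$se_W1 <- outer(ca$z, dpre1); g$se_b1 <- dpre1
  }
  dz <- dz + drop(p$se_W1 %*% dpre1)

  nA <- nrow(ca$A)
  dA <- matrix(dz / nA, nA, C, byrow = TRUE)

  # backbone
  dc3 <- dA * (ca$c3$out > 0)
  bk3 <- conv3_backward(dc3, ca$c3$patches, p$conv3_W, ca$H2, ca$W2, "zero",
    need_dx = TRUE, need_dw = need_params)
  if (need_params) { g$conv3_W <- bk3$dK; g$conv3_b <- bk3$db }
  da2 <- maxpool2_backward(bk3$dx, ca$pl2, ca$H1, ca$W1)
  dc2 <- da2 * (ca$c2$out > 0)
  bk2 <- conv3_backward(dc2, ca$c2$patches, p$conv2_W, ca$H1, ca$W1, "zero",
    need_dx = TRUE, need_dw = need_params)
  if (need_params) { g$conv2_W <- bk2$dK; g$conv2_b <- bk2$db }
  da1 <- maxpool2_backward(bk2$dx, ca$pl1, ca$H, ca$W)
  dc1 <- da1 * (ca$c1$out > 0)
  bk1 <- conv3_backward(dc1, ca$c1$patches, p$conv1_W, ca$H, ca$W, "zero",
    need_dx = need_input, need_dw = need_params)
  if (need_params) { g$conv1_W <- bk1$dK; g$conv1_b <- bk1$db }

  d_input <- NULL
  if (need_input) {
    dxm <- bk1$dx
    if (!is.null(dxm_edge)) dxm <- dxm + dxm_edge
    d_input <- array(dxm, dim = c(ca$H, ca$W, 3L))
  }
  list(grads = g, d_input = d_input,
    dA = dA, A = ca$A, feat_h = ca$H2, feat_w = ca$W2)
}

# Stable categorical cross-entropy from logits for a one-hot row y.
ce_from_logits <- function(logits, y) {
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  -(sum(logits * y) - lse)
}

accumulate_grads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) total[[nm]] <- total[[nm]] + g[[nm]]
  total
}

# ---- callbacks -------------------------------------------------------------

#' Early-stopping state machine
#'
#' Tracks the best monitored value; after `patience` consecutive epochs
#' without improvement, signals a stop. Pure state transition, so the
#' contract is testable on manufactured monitor sequences.
#'
#' @param patience Number of non-improving epochs tolerated.
#' @param restore_best Restore weights from the best epoch on stop?
#' @return State list; update with [early_stopping_step()].
#' @export
early_stopping_state <- function(patience = 5L, restore_best = TRUE) {
  list(patience = patience, restore_best = restore_best,
    best = Inf, best_epoch = 0L, wait = 0L, stop = FALSE)
}

#' @rdname early_stopping_state
#' @param state State from [early_stopping_state()].
#' @param value Monitored value (lower is better).
#' @param epoch Current epoch number.
#' @export
early_stopping_step <- function(state, value, epoch) {
  if (value < state$best) {
    state$best <- value
    state$best_epoch <- epoch
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) state$stop <- TRUE
  }
  state
}

#' Learning-rate plateau scheduler
#'
#' Multiplies the learning rate by `factor` after `patience` consecutive
#' epochs without improvement of the monitored value, never dropping below
#' `min_lr`.
#'
#' @param lr Initial learning rate.
#' @param factor Multiplicative reduction factor.
#' @param patience Stagnant epochs before each reduction.
#' @param min_lr Lower bound for the learning rate.
#' @return State list; update with [reduce_lr_step()].
#' @export
reduce_lr_state <- function(lr, factor = 0.5, patience = 3L, min_lr = 1e-6) {
  list(lr = lr, factor = factor, patience = patience, min_lr = min_lr,
    best = Inf, wait = 0L)
}

#' @rdname reduce_lr_state
#' @param state State from [reduce_lr_state()].
#' @param value Monitored value (lower is better).
#' @export
reduce_lr_step <- function(state, value) {
  if (value < state$best) {
    state$best <- value
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$min_lr)
      state$wait <- 0L
    }
  }
  state
}

# ---- training --------------------------------------------------------------

#' Train the dual-branch model
#'
#' Minimizes categorical cross-entropy with Adam at
#' `model$cfg$learning_rate`, monitoring validation loss for early stopping
#' and learning-rate reduction. All randomness (shuffling via the streams,
#' dropout here) descends from fixed seeds, so two runs with the same seeds
#' are identical.
#'
#' @param model A `sobelnet_model` from [build_model()].
#' @param train_stream,val_stream Streams from [make_stream()] (train /
#'   eval mode respectively), yielding normalized batches.
#' @param epochs Override `model$cfg$epochs` if given.
#' @param verbose Print one line per epoch?
#' @return The trained model; `$history` holds a `sobelnet_history` tibble
#'   (epoch, loss, accuracy, val_loss, val_accuracy, lr) with attributes
#'   `stopped_epoch` and `best_epoch`.
#' @export
train_model <- function(model, train_stream, val_stream, epochs = NULL,
                        verbose = FALSE) {
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  steps <- cfg$steps_per_epoch %||% train_stream$n_batches
  trainable <- trainable_names(model)
  opt <- adam_init(model$params)
  es <- early_stopping_state(cfg$early_stop$patience %||% 5L,
    isTRUE(cfg$early_stop$restore_best %||% TRUE))
  rl <- reduce_lr_state(cfg$learning_rate,
    cfg$lr_plateau$factor %||% 0.5, cfg$lr_plateau$patience %||% 3L,
    cfg$lr_plateau$min_lr %||% 1e-6)
  best_params <- model$params
  rows <- list()
  train_stream$reset()

  with_seed(mix_seed(cfg$seed, 202), {
    for (epoch in seq_len(epochs)) {
      ep_loss <- 0; ep_correct <- 0L; ep_n <- 0L
      for (st in seq_len(steps)) {
        batch <- train_stream$next_batch()
        B <- dim(batch$x)[1L]
        grads <- NULL
        for (b in seq_len(B)) {
          fw <- fwd_image(model, batch$x[b, , , ], training = TRUE)
          y <- batch$y[b, ]
          ep_loss <- ep_loss + ce_from_logits(fw$logits, y)
          ep_correct <- ep_correct + as.integer(which.max(fw$probs) == which.max(y))
          dlogits <- (fw$probs - y) / B
          bw <- bwd_image(model, fw$cache, dlogits)
          grads <- accumulate_grads(grads, bw$grads)
        }
        ep_n <- ep_n + B
        up <- adam_step(model$params, grads, opt, rl$lr, trainable)
        model$params <- up$params
        opt <- up$state
      }
      train_loss <- ep_loss / ep_n
      if (!is.finite(train_loss)) {
        abort(sprintf("Non-finite training loss at epoch %d; reduce the learning rate.", epoch),
          class = "sobelnet_error_numeric")
      }
      ev <- eval_pass(model, val_stream)
      rows[[epoch]] <- tibble(epoch = epoch, loss = train_loss,
        accuracy = ep_correct / ep_n, val_loss = ev$loss,
        val_accuracy = ev$accuracy, lr = rl$lr)
      if (verbose) {
        message(sprintf("epoch %2d  loss %.4f acc %.4f  val_loss %.4f val_acc %.4f  lr %.2e",
          epoch, train_loss, ep_correct / ep_n, ev$loss, ev$accuracy, rl$lr))
      }
      es <- early_stopping_step(es, ev$loss, epoch)
      if (es$best_epoch == epoch) best_params <- model$params
      rl <- reduce_lr_step(rl, ev$loss)
      if (es$stop) break
    }
  })
  if (es$restore_best && es$best_epoch > 0L) model$params <- best_params
  history <- dplyr::bind_rows(rows)
  attr(history, "stopped_epoch") <- nrow(history)
  attr(history, "best_epoch") <- es$best_epoch
  class(history) <- c("sobelnet_history", class(history))
  model$history <- history
  model
}

# One full evaluation epoch over an eval-mode stream.
eval_pass <- function(model, stream) {
  stream$reset()
  loss <- 0; correct <- 0L; n <- 0L
  probs <- list(); labels <- integer()
  for (i in seq_len(stream$n_batches)) {
    batch <- stream$next_batch()
    B <- dim(batch$x)[1L]
    for (b in seq_len(B)) {
      fw <- fwd_image(model, batch$x[b, , , ], training = FALSE)
      y <- batch$y[b, ]
      loss <- loss + ce_from_logits(fw$logits, y)
      correct <- correct + as.integer(which.max(fw$probs) == which.max(y))
      probs[[n + b]] <- fw$probs
      labels[n + b] <- which.max(y)
    }
    n <- n + B
  }
  list(loss = loss / n, accuracy = correct / n,
    probs = do.call(rbind, probs), labels = labels)
}

#' Predict class probabilities and labels
#'
#' @param object A `sobelnet_model`.
#' @param newdata A `batch_stream`, a `B x H x W x 3` normalized array, or a
#'   single `H x W x 3` normalized image.
#' @param ... Unused.
#' @return Tibble with one `.prob_<class>` column per class and
#'   `.pred_class`; hard labels are the argmax, ties resolved to the lowest
#'   class index.
#' @export
predict.sobelnet_model <- function(object, newdata, ...) {
  if (inherits(newdata, "batch_stream")) {
    newdata$reset()
    xs <- list()
    for (i in seq_len(newdata$n_batches)) {
      b <- newdata$next_batch()
      xs[[i]] <- b$x
    }
    x <- do.call(function(...) abind_first(list(...)), xs)
  } else if (length(dim(newdata)) == 3L) {
    x <- array(newdata, dim = c(1L, dim(newdata)))
  } else {
    x <- newdata
  }
  B <- dim(x)[1L]
  probs <- matrix(0, B, object$cfg$num_classes)
  for (b in seq_len(B)) {
    probs[b, ] <- fwd_image(object, x[b, , , ], training = FALSE)$probs
  }
  colnames(probs) <- object$classes
  out <- as_tibble(probs, .name_repair = ~ paste0(".prob_", .x))
  out$.pred_class <- factor(object$classes[max.col(probs, ties.method = "first")],
    levels = object$classes)
  out
}

abind_first <- function(lst) {
  d <- dim(lst[[1L]])
  total <- sum(vapply(lst, function(a) dim(a)[1L], integer(1)))
  out <- array(0, dim = c(total, d[-1L]))
  at <- 0L
  for (a in lst) {
    B <- dim(a)[1L]
    out[at + seq_len(B), , , ] <- a
    at <- at + B
  }
  out
}

#' @export
print.sobelnet_model <- function(x, ...) {
  cat("Dual-branch edge-aware classifier (tiny backbone)\n")
  cat(sprintf("  input %dx%dx3; backbone filters %s; SE ratio %d; edge filters %d\n",
    x$cfg$img_size, x$cfg$img_size, paste(backbone_filters, collapse = "/"),
    x$se_cfg$ratio, x$edge_cfg$conv_filters))
  cat(sprintf("  dense %d -> dropout %.2f -> softmax over {%s}\n",
    x$cfg$dense_units, x$cfg$dropout_rate, paste(x$classes, collapse = ", ")))
  cat(sprintf("  parameters: %d (%d trainable)\n",
    n_parameters(x), n_parameters(x, trainable_only = TRUE)))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; final val_accuracy %.4f\n",
      nrow(x$history), tail(x$history$val_accuracy, 1)))
  }
  invisible(x)
}
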