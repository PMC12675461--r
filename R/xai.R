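# Attribution methods. All four operate through three narrow capability
# generics -- class probabilities, input-space gradients, and feature-map
# gradients -- with methods for the package's own model and for small
# analytic reference models whose attributions are known in closed form
# (used to validate the implementations).

# ---- capability generics ---------------------------------------------------

#' Class probabilities for a list of images
#' @param model A `sobelnet_model`, or a plain `function(list_of_images)`
#'   returning an n x K probability matrix (or a probability vector for the
#'   first class).
#' @param imgs List of image arrays.
#' @return n x K probability matrix.
#' @export
xai_predict <- function(model, imgs) UseMethod("xai_predict")

#' @export
xai_predict.sobelnet_model <- function(model, imgs) {
  t(vapply(imgs, function(im) fwd_image(model, im, training = FALSE)$probs,
    numeric(model$cfg$num_classes)))
}

#' @export
xai_predict.function <- function(model, imgs) {
  out <- model(imgs)
  if (is.null(dim(out))) out <- cbind(out, 1 - out)
  as.matrix(out)
}

#' Gradient of a class score with respect to the input image
#' @param model Model handle.
#' @param img Image array.
#' @param class_index Integer class index.
#' @return `list(score, grad)` with `grad` shaped like `img`.
#' @export
xai_input_gradient <- function(model, img, class_index) UseMethod("xai_input_gradient")

#' @export
xai_input_gradient.sobelnet_model <- function(model, img, class_index) {
  fw <- fwd_image(model, img, training = FALSE)
  dlogits <- numeric(length(fw$logits))
  dlogits[class_index] <- 1
  bw <- bwd_image(model, fw$cache, dlogits, need_input = TRUE, need_params = FALSE)
  list(score = fw$logits[class_index], grad = bw$d_input)
}

#' @export
xai_input_gradient.default <- function(model, img, class_index) {
  abort("Model handle does not expose input gradients.",
    class = "sobelnet_error_validation")
}

#' Activations and gradient of a class score at a convolutional layer
#' @param model Model handle.
#' @param img Image array.
#' @param class_index Integer class index.
#' @param layer Layer name; the package model exposes `"backbone_final"`
#'   (the last backbone feature map, the standard CAM target).
#' @return `list(A, dA)`: h x w x K activation array and like-shaped gradient.
#' @export
xai_featmap_gradient <- function(model, img, class_index, layer = "backbone_final") {
  UseMethod("xai_featmap_gradient")
}

#' @export
xai_featmap_gradient.sobelnet_model <- function(model, img, class_index,
                                                layer = "backbone_final") {
  if (!identical(layer, "backbone_final")) {
    abort(sprintf("Unknown layer '%s'; available: \"backbone_final\".", layer),
      class = "sobelnet_error_validation")
  }
  fw <- fwd_image(model, img, training = FALSE)
  dlogits <- numeric(length(fw$logits))
  dlogits[class_index] <- 1
  bw <- bwd_image(model, fw$cache, dlogits, need_input = FALSE, need_params = FALSE)
  K <- ncol(bw$A)
  list(A = array(bw$A, dim = c(bw$feat_h, bw$feat_w, K)),
    dA = array(bw$dA, dim = c(bw$feat_h, bw$feat_w, K)))
}

# ---- analytic reference models --------------------------------------------

#' Analytic linear pixel model
#'
#' Class score `k` is the inner product of the image with a fixed weight
#' array: `score_k = sum(W_k * x)`. Its vanilla-saliency map is exactly the
#' per-pixel channel-max of `|W_k|`, making it a closed-form reference for
#' gradient-based attributions.
#'
#' @param weights List of weight arrays, one per class, each shaped like the
#'   input image.
#' @return A `linear_pixel_model`.
#' @export
linear_pixel_model <- function(weights) {
  structure(list(weights = weights), class = "linear_pixel_model")
}

#' @export
xai_predict.linear_pixel_model <- function(model, imgs) {
  scores <- t(vapply(imgs, function(im) {
    vapply(model$weights, function(w) sum(w * im), numeric(1))
  }, numeric(length(model$weights))))
  softmax_row(scores)
}

#' @export
xai_input_gradient.linear_pixel_model <- function(model, img, class_index) {
  list(score = sum(model$weights[[class_index]] * img),
    grad = model$weights[[class_index]])
}

#' Analytic single-map activation model
#'
#' The feature map is a fixed array and class `k`'s score is the spatial
#' mean of activation map `map_index[k]`. Both Grad-CAM and Grad-CAM++
#' provably reduce to `relu(A[,,map_index])` (up to normalization) on this
#' model.
#'
#' @param A h x w x K fixed activation array.
#' @param map_index Integer vector: which map carries each class's score.
#' @return An `analytic_map_model`.
#' @export
analytic_map_model <- function(A, map_index = 1L) {
  structure(list(A = A, map_index = as.integer(map_index)),
    class = "analytic_map_model")
}

#' @export
xai_featmap_gradient.analytic_map_model <- function(model, img, class_index,
                                                    layer = "backbone_final") {
  k <- model$map_index[class_index]
  dA <- array(0, dim = dim(model$A))
  dA[, , k] <- 1 / (dim(model$A)[1L] * dim(model$A)[2L])
  list(A = model$A, dA = dA)
}

# ---- attribution container -------------------------------------------------

new_attribution <- function(map, method, target_class, raw_range = range(map)) {
  structure(map, class = c("sobelnet_attribution", "matrix"),
    method = method, target_class = target_class, raw_range = raw_range)
}

#' @export
print.sobelnet_attribution <- function(x, ...) {
  cat(sprintf("<%s attribution, %d x %d, class %s, values [%.4g, %.4g]>\n",
    attr(x, "method"), nrow(x), ncol(x), attr(x, "target_class"),
    min(x), max(x)))
  invisible(x)
}

resolve_class_index <- function(model, class) {
  if (inherits(model, "sobelnet_model") && is.character(class)) {
    idx <- match(class, model$classes)
    if (is.na(idx)) {
      abort(sprintf("Unknown class '%s'; model classes: %s.", class,
        paste(model$classes, collapse = ", ")), class = "sobelnet_error_validation")
    }
    return(idx)
  }
  as.integer(class)
}

# Min-max normalize to [0, 1]; constant maps normalize to all-zero.
minmax_norm <- function(m) {
  lo <- min(m); hi <- max(m)
  if (hi - lo < 1e-12) return(m * 0)
  (m - lo) / (hi - lo)
}

# ---- the four methods ------------------------------------------------------

#' Vanilla saliency
#'
#' Per-pixel relevance is the channel-wise maximum of the absolute gradient
#' of the target class score with respect to the input pixels.
#'
#' @param model Model handle exposing input gradients.
#' @param img Input image (normalized, for the package model).
#' @param class Class name (package model) or index.
#' @return A `sobelnet_attribution` matrix (same spatial size as the input,
#'   nonnegative).
#' @export
vanilla_saliency <- function(model, img, class) {
  idx <- resolve_class_index(model, class)
  gr <- xai_input_gradient(model, img, idx)$grad
  if (length(dim(gr)) == 3L) {
    m <- apply(abs(gr), c(1L, 2L), max)
  } else {
    m <- abs(gr)
  }
  new_attribution(m, "vanilla_saliency", class)
}

#' Grad-CAM
#'
#' Channel weights are the spatial means of the class-score gradient at the
#' target layer; the map is the rectified weighted sum of activation maps,
#' bilinearly upsampled to the input size and min-max normalized to
#' `[0, 1]` (constant maps normalize to all-zero).
#'
#' @inheritParams vanilla_saliency
#' @param layer Target layer name (default `"backbone_final"`).
#' @param out_size Output spatial size; defaults to the input image's.
#' @return A `sobelnet_attribution` in `[0, 1]`.
#' @export
grad_cam <- function(model, img, class, layer = "backbone_final",
                     out_size = NULL) {
  idx <- resolve_class_index(model, class)
  fg <- xai_featmap_gradient(model, img, idx, layer)
  alpha <- apply(fg$dA, 3L, mean)
  K <- dim(fg$A)[3L]
  cam <- matrix(0, dim(fg$A)[1L], dim(fg$A)[2L])
  for (k in seq_len(K)) cam <- cam + alpha[k] * fg$A[, , k]
  cam <- relu(cam)
  out_size <- out_size %||% dim(img)[1:2]
  up <- resize_bilinear(cam, out_size[1L], out_size[length(out_size)])
  new_attribution(minmax_norm(up), "grad_cam", class, raw_range = range(cam))
}

#' Grad-CAM++
#'
#' Uses the closed-form location-dependent weights derived from first-order
#' layer gradients under the exponential-score formulation:
#' `alpha = g^2 / (2 g^2 + S_k g^3)` with `S_k` the spatial sum of map `k`,
#' and channel weight `w_k = sum(alpha * relu(g))`. Sharper localization
#' than plain Grad-CAM when several regions activate a channel.
#'
#' @inheritParams grad_cam
#' @return A `sobelnet_attribution` in `[0, 1]`.
#' @export
grad_cam_pp <- function(model, img, class, layer = "backbone_final",
                        out_size = NULL) {
  idx <- resolve_class_index(model, class)
  fg <- xai_featmap_gradient(model, img, idx, layer)
  K <- dim(fg$A)[3L]
  cam <- matrix(0, dim(fg$A)[1L], dim(fg$A)[2L])
  for (k in seq_len(K)) {
    g <- fg$dA[, , k]
    g2 <- g * g
    g3 <- g2 * g
    denom <- 2 * g2 + sum(fg$A[, , k]) * g3
    alpha <- ifelse(abs(denom) > 1e-12, g2 / denom, 0)
    w <- sum(alpha * relu(g))
    cam <- cam + w * fg$A[, , k]
  }
  cam <- relu(cam)
  out_size <- out_size %||% dim(img)[1:2]
  up <- resize_bilinear(cam, out_size[1L], out_size[length(out_size)])
  new_attribution(minmax_norm(up), "grad_cam_pp", class, raw_range = range(cam))
}

# ---- LIME ------------------------------------------------------------------

#' SLIC-style superpixel segmentation
#'
#' Grid-initialized k-means over (row, column, intensity) features; spatial
#' coordinates are scaled by the expected segment spacing and intensity by
#' `1 / compactness`, so larger compactness yields more regular segments.
#' Deterministic (no randomness). Segment connectivity is not enforced.
#'
#' @param img Image array (any range; intensity is rescaled internally).
#' @param n_segments Requested number of segments (>= 2).
#' @param compactness Spatial-versus-intensity trade-off.
#' @param n_iter k-means iterations.
#' @return Integer H x W label matrix with labels `1..m`, `m <= n_segments`.
#' @export
slic_superpixels <- function(img, n_segments = 50, compactness = 0.2, n_iter = 5) {
  if (n_segments < 2) {
    abort("`n_segments` must be >= 2.", class = "sobelnet_error_validation")
  }
  g <- luminance(unclass(img))
  rngv <- max(g) - min(g)
  g <- if (rngv > 1e-12) (g - min(g)) / rngv else g * 0
  H <- nrow(g); W <- ncol(g)
  S <- sqrt(H * W / n_segments)
  ny <- max(1L, round(H / S)); nx <- max(1L, ceiling(n_segments / ny))
  cy <- (seq_len(ny) - 0.5) * H / ny
  cx <- (seq_len(nx) - 0.5) * W / nx
  centers <- cbind(rep(cy, times = nx), rep(cx, each = ny))
  centers <- centers[seq_len(min(nrow(centers), n_segments)), , drop = FALSE]
  ci <- g[cbind(pmin(pmax(round(centers[, 1]), 1), H),
    pmin(pmax(round(centers[, 2]), 1), W))]
  yy <- rep(seq_len(H), times = W); xx <- rep(seq_len(W), each = H)
  gv <- as.vector(g)
  lab <- integer(H * W)
  for (it in seq_len(n_iter)) {
    d <- matrix(Inf, H * W, nrow(centers))
    for (k in seq_len(nrow(centers))) {
      d[, k] <- ((yy - centers[k, 1]) / S)^2 + ((xx - centers[k, 2]) / S)^2 +
        ((gv - ci[k]) / compactness)^2
    }
    lab <- max.col(-d, ties.method = "first")
    for (k in seq_len(nrow(centers))) {
      sel <- lab == k
      if (any(sel)) {
        centers[k, 1] <- mean(yy[sel]); centers[k, 2] <- mean(xx[sel])
        ci[k] <- mean(gv[sel])
      }
    }
  }
  keep <- sort(unique(lab))
  lab <- match(lab, keep)
  matrix(lab, H, W)
}

#' LIME superpixel explanation
#'
#' Segments the image, draws binary segment on/off perturbations (off
#' segments replaced by a baseline fill), collects model probabilities for
#' the target class, and fits a distance-weighted ridge surrogate on the
#' binary design (kernel `exp(-d^2 / width^2)` of the cosine distance to the
#' unperturbed mask). Deterministic given `seed`.
#'
#' @param model Model handle exposing probabilities ([xai_predict()]): a
#'   `sobelnet_model` or a plain function.
#' @param img Image array to explain.
#' @param class Class name/index; defaults to the model's prediction.
#' @param n_segments Superpixel count (>= 2).
#' @param n_samples Number of random perturbations (>= number of segments).
#' @param k Size of the positive top-k mask.
#' @param seed Seed for mask sampling.
#' @param kernel_width Exponential-kernel width on cosine distance.
#' @param baseline Fill value for switched-off segments; default the image
#'   mean.
#' @param segments Optional precomputed label matrix (overrides
#'   `n_segments`).
#' @param perturbations Optional n x m 0/1 design matrix; overrides random
#'   sampling (e.g. the exhaustive design for small m).
#' @param ridge Ridge penalty stabilising the weighted least squares.
#' @return A `sobelnet_lime`: list with `segments`, `weights` (tibble
#'   `segment`, `weight`), `intercept`, `top_k` (segment ids), `top_k_mask`
#'   (logical H x W), `class`.
#' @export
lime_explain <- function(model, img, class = NULL, n_segments = 50,
                         n_samples = 200, k = 5, seed = 1L,
                         kernel_width = 0.25, baseline = NULL,
                         segments = NULL, perturbations = NULL,
                         ridge = 1e-6) {
  segs <- segments %||% slic_superpixels(img, n_segments)
  m <- max(segs)
  if (is.null(perturbations) && n_samples < m) {
    abort("`n_samples` must be at least the number of segments.",
      class = "sobelnet_error_validation")
  }
  base <- baseline %||% mean(img)
  idx_by_seg <- split(seq_len(length(segs)), as.vector(segs))

  cls <- if (is.null(class)) {
    which.max(xai_predict(model, list(img))[1L, ])
  } else {
    resolve_class_index(model, class)
  }

  masks <- perturbations %||% with_seed(mix_seed(seed, 404), {
    mm <- matrix(as.numeric(runif(n_samples * m) < 0.5), n_samples, m)
    mm[1L, ] <- 1 # anchor with the unperturbed image
    mm
  })
  storage.mode(masks) <- "double"

  d <- dim(img)
  imgs <- lapply(seq_len(nrow(masks)), function(i) {
    pim <- img
    off <- which(masks[i, ] == 0)
    if (length(off)) {
      lin <- unlist(idx_by_seg[off], use.names = FALSE)
      if (length(d) == 3L) {
        for (c in seq_len(d[3L])) pim[lin + (c - 1L) * d[1L] * d[2L]] <- base
      } else {
        pim[lin] <- base
      }
    }
    pim
  })
  y <- xai_predict(model, imgs)[, cls]

  frac_on <- rowSums(masks) / m
  cosd <- 1 - sqrt(frac_on) # cosine distance of a 0/1 mask to the all-ones mask
  w <- exp(-(cosd^2) / kernel_width^2)

  X <- unname(cbind(1, masks))
  XtW <- t(X * w)
  beta <- solve(XtW %*% X + diag(c(0, rep(ridge, m))), XtW %*% y)
  weights <- unname(drop(beta)[-1L])

  pos <- order(weights, decreasing = TRUE)
  pos <- pos[weights[pos] > 0]
  top <- head(pos, k)
  mask_top <- matrix(as.vector(segs) %in% top, nrow(segs), ncol(segs))

  structure(list(
    segments = segs,
    weights = tibble(segment = seq_len(m), weight = weights),
    intercept = drop(beta)[1L],
    top_k = top, top_k_mask = mask_top,
    class = cls, kernel_width = kernel_width, baseline = base
  ), class = "sobelnet_lime")
}

#' @export
print.sobelnet_lime <- function(x, ...) {
  cat(sprintf("<LIME explanation: %d segments, class %s>\n",
    nrow(x$weights), x$class))
  top <- dplyr::arrange(x$weights, dplyr::desc(.data$weight))
  print(head(top, 5))
  invisible(x)
}

#' Render an attribution overlay to a PNG file
#'
#' Blends a color-mapped relevance heatmap onto the grayscale base image:
#' `overlay = (1 - alpha) * gray + alpha * colormap(map)`.
#'
#' @param img Raw-range base image.
#' @param map Attribution map in `[0, 1]` (same spatial size as `img`).
#' @param out_path PNG destination.
#' @param alpha Heatmap opacity.
#' @return `out_path`, invisibly.
#' @export
render_overlay <- function(img, map, out_path, alpha = 0.45) {
  base <- luminance(unclass(img)) / 255
  hm <- jet_colormap(clamp01(unclass(map)))
  out <- array(0, dim = c(dim(base), 3L))
  for (c in 1:3) out[, , c] <- (1 - alpha) * base + alpha * hm[, , c]
  png::writePNG(clamp01(out), target = out_path)
  invisible(out_path)
}
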