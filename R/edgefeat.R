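# Edge Feature Block: fixed Sobel kernels approximate first-order image
# gradients, their magnitude gives an edge-strength map, a single learnable
# 3x3 convolution with rectifier extracts edge-level features, and global
# average pooling compresses them to a compact vector.

# Standard Sobel kernels applied as cross-correlation. S_x responds to
# horizontal intensity change (vertical edges), S_y = t(S_x) to vertical.
sobel_kernels <- function() {
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # columns -1,0,+1 in x
  list(sx = sx, sy = t(sx))
}

#' Edge-branch configuration
#'
#' @param filter_type Only `"sobel"` is implemented.
#' @param trainable_filters Should the Sobel kernels be updated during
#'   training? Default `FALSE` (fixed classical filters).
#' @param conv_filters Number of learnable 3x3 filters applied to the edge
#'   magnitude map (default 32).
#' @param activation Only `"relu"`.
#' @return An `edge_config` list.
#' @export
edge_config <- function(filter_type = "sobel", trainable_filters = FALSE,
                        conv_filters = 32L, activation = "relu") {
  if (!identical(filter_type, "sobel")) {
    abort("Only filter_type = \"sobel\" is supported.", class = "sobelnet_error_validation")
  }
  if (conv_filters < 1L) {
    abort("`conv_filters` must be >= 1.", class = "sobelnet_error_validation")
  }
  structure(list(filter_type = filter_type,
    trainable_filters = isTRUE(trainable_filters),
    conv_filters = as.integer(conv_filters), activation = activation),
    class = "edge_config")
}

#' Sobel image gradients
#'
#' Cross-correlates a single-channel image with the Sobel kernels; borders
#' use replicate (nearest-pixel) padding so outputs keep the input's spatial
#' size. Multi-channel inputs are first reduced to luminance.
#'
#' @param img 2-D matrix or H x W x C array.
#' @return `list(gx, gy)` of H x W gradient matrices.
#' @export
sobel_gradients <- function(img) {
  g <- luminance(unclass(img))
  H <- nrow(g); W <- ncol(g)
  if (H < 3L || W < 3L) {
    abort("Input must be at least 3 x 3.", class = "sobelnet_error_validation")
  }
  ks <- sobel_kernels()
  xm <- matrix(g, H * W, 1L)
  kx <- array(ks$sx, dim = c(3L, 3L, 1L, 1L))
  ky <- array(ks$sy, dim = c(3L, 3L, 1L, 1L))
  gx <- conv3_forward(xm, H, W, kx, pad = "replicate")$out
  gy <- conv3_forward(xm, H, W, ky, pad = "replicate")$out
  list(gx = matrix(gx, H, W), gy = matrix(gy, H, W))
}

#' Gradient magnitude
#'
#' `G = sqrt(Gx^2 + Gy^2)` elementwise.
#'
#' @param gx,gy Equal-shape gradient matrices.
#' @return Nonnegative matrix of edge strengths.
#' @export
gradient_magnitude <- function(gx, gy) {
  if (!identical(dim(gx), dim(gy))) {
    abort("`gx` and `gy` must have identical shapes.", class = "sobelnet_error_validation")
  }
  sqrt(gx^2 + gy^2)
}

#' Initialize edge-branch weights
#'
#' @param cfg An [edge_config()].
#' @return `list(W = 3 x 3 x 1 x conv_filters kernel, b = bias vector)`.
#' @export
init_edge_weights <- function(cfg) {
  list(W = init_conv(1L, cfg$conv_filters), b = numeric(cfg$conv_filters))
}

#' Compact edge feature vector
#'
#' Sobel gradients -> magnitude -> one learnable 3x3 convolution with
#' rectifier (replicate padding) -> global average pooling. Because the
#' branch starts from image gradients, the output is invariant to adding a
#' constant to the input image.
#'
#' @param img Image (any range; gradients are range-covariant).
#' @param cfg An [edge_config()].
#' @param weights Weights from [init_edge_weights()] (or trained).
#' @return Numeric vector of length `cfg$conv_filters`: the spatial mean of
#'   each post-activation map.
#' @export
edge_feature_vector <- function(img, cfg = edge_config(), weights = init_edge_weights(cfg)) {
  if (!identical(dim(weights$W)[4L], cfg$conv_filters) || length(weights$b) != cfg$conv_filters) {
    abort("Edge weights do not match `cfg$conv_filters`.", class = "sobelnet_error_validation")
  }
  gr <- sobel_gradients(img)
  G <- gradient_magnitude(gr$gx, gr$gy)
  H <- nrow(G); W <- ncol(G)
  a <- relu(conv3_forward(matrix(G, H * W, 1L), H, W, weights$W, weights$b,
    pad = "replicate")$out)
  colMeans(a)
}
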