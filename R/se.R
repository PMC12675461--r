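# Squeeze-and-excitation channel recalibration: global average pooling
# produces a channel descriptor (squeeze), a two-layer bottleneck with
# rectifier and sigmoid produces per-channel gates in (0, 1) (excite), and
# the feature map is rescaled channel-wise (reweight).

#' Squeeze-and-excitation configuration
#'
#' @param ratio Bottleneck reduction divisor `r` (default 16, the standard
#'   choice); bottleneck width is `ceiling(C / r)`.
#' @param channels Number of feature-map channels `C`.
#' @return An `se_config` list.
#' @export
se_config <- function(ratio = 16L, channels = 64L) {
  if (ratio < 1L) abort("`ratio` must be >= 1.", class = "sobelnet_error_validation")
  structure(list(ratio = as.integer(ratio), channels = as.integer(channels),
    bottleneck = max(1L, as.integer(ceiling(channels / ratio)))),
    class = "se_config")
}

as_featmat <- function(feat) {
  if (is.matrix(feat)) return(feat)
  if (length(dim(feat)) == 3L) {
    return(matrix(feat, dim(feat)[1L] * dim(feat)[2L], dim(feat)[3L]))
  }
  abort("Feature map must be an H x W x C array or (H*W) x C matrix.",
    class = "sobelnet_error_validation")
}

#' Squeeze: per-channel spatial mean
#'
#' @param feat H x W x C array or (H*W) x C matrix of activations.
#' @return Length-C channel descriptor.
#' @export
se_squeeze <- function(feat) {
  fm <- as_featmat(feat)
  if (nrow(fm) == 0L) {
    abort("Feature map has empty spatial dimensions.", class = "sobelnet_error_validation")
  }
  colMeans(fm)
}

#' Initialize excitation weights
#'
#' @param cfg An [se_config()].
#' @return `list(W1, b1, W2, b2)` shaped `C -> ceiling(C/r) -> C`.
#' @export
init_se_weights <- function(cfg) {
  list(
    W1 = init_dense(cfg$channels, cfg$bottleneck), b1 = numeric(cfg$bottleneck),
    W2 = init_dense(cfg$bottleneck, cfg$channels), b2 = numeric(cfg$channels)
  )
}

#' Excite: bottleneck gating
#'
#' `s = sigmoid(W2 %*% relu(W1 %*% z))` (biases included); every gate lies
#' strictly in (0, 1).
#'
#' @param z Length-C channel descriptor.
#' @param weights Weights from [init_se_weights()].
#' @param cfg An [se_config()].
#' @return Length-C gate vector.
#' @export
se_excite <- function(z, weights, cfg) {
  if (length(z) != cfg$channels ||
      !identical(dim(weights$W1), c(cfg$channels, cfg$bottleneck)) ||
      !identical(dim(weights$W2), c(cfg$bottleneck, cfg$channels))) {
    abort("Excitation weight shapes do not match the configuration.",
      class = "sobelnet_error_validation")
  }
  h <- relu(drop(z %*% weights$W1) + weights$b1)
  drop(sigmoid(h %*% weights$W2 + weights$b2))
}

#' Reweight: channel-wise rescaling
#'
#' Multiplies channel `c` of the feature map by gate `s[c]`. With gates in
#' (0, 1) this is strictly contractive per channel, and commutes with the
#' squeeze: `se_squeeze(se_reweight(F, s)) == s * se_squeeze(F)`.
#'
#' @param feat H x W x C array or (H*W) x C matrix.
#' @param s Length-C gate vector.
#' @return Rescaled feature map, same shape as the input.
#' @export
se_reweight <- function(feat, s) {
  fm <- as_featmat(feat)
  if (length(s) != ncol(fm)) {
    abort("Gate length must equal the channel count.", class = "sobelnet_error_validation")
  }
  out <- fm * rep(s, each = nrow(fm))
  if (length(dim(feat)) == 3L) array(out, dim = dim(feat)) else out
}
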