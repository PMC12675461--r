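# Minimal CNN engine: 3x3 same-padding convolution (im2col), 2x2 max pooling,
# dense layers, softmax cross-entropy, and Adam. Activations are stored as
# (H*W) x C matrices in column-major spatial order (index = i + (j-1)*H), so
# convolutions become one gather plus one BLAS matrix multiply per layer.
# Every forward caches what its backward needs; backward is exact, which the
# test suite verifies against central finite differences.

.conv_idx_cache <- new.env(parent = emptyenv())

# For each output pixel, linear indices of its 3x3 patch in the padded image.
# Column k corresponds to kernel entry (u, v) with u fast (column-major), i.e.
# patch column k matches as.vector(K[, , cin, cout])[k]: cross-correlation.
conv_idx <- function(H, W) {
  key <- paste0(H, "x", W)
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L
  base <- rep.int(seq_len(H), W) + (rep(seq_len(W), each = H) - 1L) * Hp
  idx <- matrix(0L, H * W, 9L)
  k <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      k <- k + 1L
      idx[, k] <- base + di + dj * Hp
    }
  }
  .conv_idx_cache[[key]] <- idx
  idx
}

# Gather map for replicate ("nearest") padding: padded position -> source
# linear index (edge pixels repeated).
replicate_pad_map <- function(H, W) {
  key <- paste0("rep", H, "x", W)
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  pi <- pmin(pmax(rep.int(seq_len(H + 2L) - 1L, W + 2L), 1L), H)
  pj <- pmin(pmax(rep(seq_len(W + 2L) - 1L, each = H + 2L), 1L), W)
  map <- pi + (pj - 1L) * H
  .conv_idx_cache[[key]] <- map
  map
}

interior_idx <- function(H, W) {
  key <- paste0("int", H, "x", W)
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L
  ii <- rep.int(seq_len(H) + 1L, W) + rep(seq_len(W), each = H) * Hp
  .conv_idx_cache[[key]] <- ii
  ii
}

pad3 <- function(xm, H, W, mode) {
  C <- ncol(xm)
  if (mode == "replicate") {
    xm[replicate_pad_map(H, W), , drop = FALSE]
  } else {
    out <- matrix(0, (H + 2L) * (W + 2L), C)
    out[interior_idx(H, W), ] <- xm
    out
  }
}

# Kernel array K: 3 x 3 x Cin x Cout -> weight matrix (9*Cin) x Cout with
# rows grouped by input channel, kernel entries column-major within a group.
kernel_to_mat <- function(K) {
  matrix(K, nrow = 9L * dim(K)[3L], ncol = dim(K)[4L])
}

mat_to_kernel <- function(Wm, Cin, Cout) {
  array(Wm, dim = c(3L, 3L, Cin, Cout))
}

conv3_forward <- function(xm, H, W, K, b = NULL, pad = "zero") {
  Cin <- ncol(xm)
  P <- pad3(xm, H, W, pad)
  idx <- conv_idx(H, W)
  patches <- matrix(0, H * W, 9L * Cin)
  for (c in seq_len(Cin)) {
    pc <- P[, c]
    patches[, (c - 1L) * 9L + 1:9] <- pc[idx]
  }
  out <- patches %*% kernel_to_mat(K)
  if (!is.null(b)) out <- out + matrix(b, nrow(out), length(b), byrow = TRUE)
  list(out = out, patches = patches)
}

conv3_backward <- function(dout, patches, K, H, W, pad = "zero",
                           need_dx = TRUE, need_dw = TRUE) {
  Cin <- dim(K)[3L]; Cout <- dim(K)[4L]
  dK <- NULL; db <- NULL; dx <- NULL
  if (need_dw) {
    dK <- mat_to_kernel(crossprod(patches, dout), Cin, Cout)
    db <- colSums(dout)
  }
  if (need_dx) {
    dpatches <- tcrossprod(dout, kernel_to_mat(K))
    idx <- conv_idx(H, W)
    dP <- matrix(0, (H + 2L) * (W + 2L), Cin)
    for (k in 1:9) {
      cols <- (seq_len(Cin) - 1L) * 9L + k
      tgt <- idx[, k]
      dP[tgt, ] <- dP[tgt, ] + dpatches[, cols, drop = FALSE]
    }
    if (pad == "replicate") {
      dx <- rowsum(dP, group = replicate_pad_map(H, W))
    } else {
      dx <- dP[interior_idx(H, W), , drop = FALSE]
    }
  }
  list(dK = dK, db = db, dx = dx)
}

relu <- function(x) x * (x > 0)
drelu <- function(dout, pre) dout * (pre > 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# 2x2 max pooling, stride 2 (H and W must be even).
maxpool2_forward <- function(xm, H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  i2 <- rep.int(seq_len(H2), W2)
  j2 <- rep(seq_len(W2), each = H2)
  l11 <- (2L * i2 - 1L) + (2L * j2 - 2L) * H
  lin <- cbind(l11, l11 + 1L, l11 + H, l11 + H + 1L)
  C <- ncol(xm)
  a <- xm[lin[, 1L], , drop = FALSE]
  b <- xm[lin[, 2L], , drop = FALSE]
  d <- xm[lin[, 3L], , drop = FALSE]
  e <- xm[lin[, 4L], , drop = FALSE]
  m12 <- pmax(a, b); w12 <- 1L + (b > a)
  m34 <- pmax(d, e); w34 <- 3L + (e > d)
  out <- pmax(m12, m34)
  wh <- ifelse(m34 > m12, w34, w12)
  list(out = out, which = wh, lin = lin, H2 = H2, W2 = W2)
}

maxpool2_backward <- function(dout, cache, H, W) {
  C <- ncol(dout)
  dx <- matrix(0, H * W, C)
  for (k in 1:4) {
    contrib <- dout * (cache$which == k)
    tgt <- cache$lin[, k]
    dx[tgt, ] <- dx[tgt, ] + contrib
  }
  dx
}

softmax_row <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# He-uniform initialization for a 3x3 kernel / dense matrix.
init_conv <- function(Cin, Cout) {
  limit <- sqrt(6 / (9 * Cin))
  array(runif(9 * Cin * Cout, -limit, limit), dim = c(3L, 3L, Cin, Cout))
}

init_dense <- function(n_in, n_out) {
  limit <- sqrt(6 / n_in)
  matrix(runif(n_in * n_out, -limit, limit), n_in, n_out)
}

adam_init <- function(params) {
  list(
    t = 0L,
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  )
}

adam_step <- function(params, grads, state, lr, trainable = names(params),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
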