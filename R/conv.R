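# Minimal convolution engine shared by the fixture/VGG feature extractors and
# the Siamese network: im2col + BLAS matrix multiply, with cached index
# matrices. Layouts are column-major R arrays (H, W, C, B).

.im2col_cache <- new.env(parent = emptyenv())

# Linear indices into a zero-padded (hp, wp, cin, b) array selecting every
# k x k x cin patch at stride 1, for all b batch slices stacked row-wise.
# Row order: output row fastest, then column, then batch.
im2col_indices <- function(h, w, cin, k, pad, b) {
  key <- paste(h, w, cin, k, pad, b, sep = "_")
  cached <- .im2col_cache[[key]]
  if (!is.null(cached)) return(cached)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  base_r <- rep(seq_len(h), times = w)
  base_c <- rep(seq_len(w), each = h)
  off <- expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L), ch = 0:(cin - 1L))
  plane <- hp * wp
  idx1 <- matrix(0L, h * w, k * k * cin)
  for (j in seq_len(nrow(off))) {
    idx1[, j] <- (base_r + off$dr[j]) + (base_c + off$dc[j] - 1L) * hp +
      off$ch[j] * plane
  }
  if (b > 1L) {
    offs <- (seq_len(b) - 1L) * plane * cin
    idx <- idx1[rep(seq_len(nrow(idx1)), times = b), , drop = FALSE] +
      rep(offs, each = nrow(idx1))
  } else idx <- idx1
  .im2col_cache[[key]] <- idx
  idx
}

pad_array <- function(x, pad) {
  d <- dim(x)
  if (pad == 0L) return(x)
  out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

# Same-size 2-D convolution of a batched multi-channel array with a kernel
# bank. wmat is (k*k*cin) x cout. Returns the output array and the im2col
# matrix (needed for the backward pass).
conv_forward <- function(x, wmat, k, pad, bias = NULL) {
  d <- dim(x)  # h, w, cin, b
  idx <- im2col_indices(d[1], d[2], d[3], k, pad, d[4])
  xp <- pad_array(x, pad)
  cols <- xp[idx]
  dim(cols) <- dim(idx)
  y <- cols %*% wmat
  if (!is.null(bias)) y <- sweep(y, 2L, bias, `+`)
  # cols rows are (position, batch)-ordered; rearrange to (h, w, cout, b)
  cout <- ncol(wmat)
  if (d[4] > 1L) {
    dim(y) <- c(d[1] * d[2], d[4], cout)
    y <- aperm(y, c(1, 3, 2))
  }
  list(out = array(y, c(d[1], d[2], cout, d[4])), cols = cols)
}

# Gradients of conv_forward: returns dW, db, dX. The input gradient is the
# same-size convolution of dy with the spatially flipped, channel-transposed
# kernels (valid because forward padding is (k-1)/2).
conv_backward <- function(dy, cols, wmat, x_dim, k, pad, want_dx = TRUE) {
  d <- x_dim
  cout <- ncol(wmat)
  # reorder (h*w, cout, b) -> rows (h*w*b) x cout
  dya <- array(dy, c(d[1] * d[2], cout, d[4]))
  dymat <- aperm(dya, c(1, 3, 2))
  dim(dymat) <- c(d[1] * d[2] * d[4], cout)
  dW <- crossprod(cols, dymat)
  db <- colSums(dymat)
  dx <- NULL
  if (want_dx) {
    wa <- array(wmat, c(k, k, d[3], cout))
    wf <- aperm(wa[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
    dim(wf) <- c(k * k * cout, d[3])
    dx <- conv_forward(dy, wf, k, pad)$out
    dim(dx) <- d
  }
  list(dW = dW, db = db, dX = dx)
}

# 2x2 average pooling with ceiling semantics: odd trailing rows/columns are
# handled by edge replication, so output size is ceil(n/2).
avg_pool2 <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L == 1L) { x <- x[c(seq_len(d[1]), d[1]), , , , drop = FALSE]; d <- dim(x) }
  if (d[2] %% 2L == 1L) { x <- x[, c(seq_len(d[2]), d[2]), , , drop = FALSE]; d <- dim(x) }
  o <- (x[seq(1, d[1], 2), , , , drop = FALSE] + x[seq(2, d[1], 2), , , , drop = FALSE]) / 2
  (o[, seq(1, d[2], 2), , , drop = FALSE] + o[, seq(2, d[2], 2), , , drop = FALSE]) / 2
}

relu <- function(x) { x[x < 0] <- 0; x }
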