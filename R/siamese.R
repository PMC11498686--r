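#' Siamese patch-saliency network for base-part fusion
#'
#' A twin convolutional network scores which of two co-located 16 x 16
#' patches is the more salient; scanned densely over an image pair it yields
#' a per-pixel weight map in \[0, 1\] that drives the `"snn"` base-fusion
#' mode. Both branches share all parameters. The branch is
#' conv 11x11 (pad 5) -> conv 5x5 (pad 2) -> max pool 3x3 stride 2 ->
#' conv 3x3 (pad 1), each with ReLU, followed by a fully-connected layer to
#' a 256-dimensional branch vector; the two branch vectors are concatenated
#' (512) and a final fully-connected layer with softmax gives the two-class
#' probability that the first patch is the more salient. Spatial sizes
#' through the branch are 16, 16, 8, 8. The network is trained on a
#' synthetic saliency-discrimination task ([make_patch_pairs()]): pairs of
#' textured patches where one copy is degraded by blur and/or contrast
#' reduction, the non-degraded patch being labelled salient.
#'
#' Scores are always evaluated in both input orders and averaged
#' (`s(a,b) = (p1(a,b) + p2(b,a))/2`), which makes branch-swap equivariance
#' `s(a,b) = 1 - s(b,a)` exact despite the concatenating head.
#'
#' @name siamese
NULL

.snn_channels <- c(8L, 16L, 32L)  # conv1..conv3 output channels

#' Build an initialised Siamese network
#'
#' He-scaled seeded initialisation; biases start at zero.
#'
#' @param seed Integer seed for the parameter draw.
#' @return Object of class `snn_model`.
#' @export
build_snn <- function(seed = 1L) {
  ch <- .snn_channels
  params <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(121 * ch[1], sd = sqrt(2 / 121)), 121, ch[1]),
    b1 = numeric(ch[1]),
    W2 = matrix(stats::rnorm(25 * ch[1] * ch[2], sd = sqrt(2 / (25 * ch[1]))),
                25 * ch[1], ch[2]),
    b2 = numeric(ch[2]),
    W3 = matrix(stats::rnorm(9 * ch[2] * ch[3], sd = sqrt(2 / (9 * ch[2]))),
                9 * ch[2], ch[3]),
    b3 = numeric(ch[3]),
    Wf = matrix(stats::rnorm(64 * ch[3] * 256, sd = sqrt(2 / (64 * ch[3]))),
                64 * ch[3], 256),
    bf = numeric(256),
    Wh = matrix(stats::rnorm(512 * 2, sd = sqrt(1 / 512)), 512, 2),
    bh = numeric(2)
  ))
  structure(list(params = params,
                 spec = list(patch_size = 16L, branch_output_dim = 256L,
                             channels = ch, seed = as.integer(seed))),
            class = "snn_model")
}

#' @export
print.snn_model <- function(x, ...) {
  cat(sprintf("<snn_model> 16x16 patches, conv channels %s, branch dim %d, seed %d\n",
              paste(x$spec$channels, collapse = "/"),
              x$spec$branch_output_dim, x$spec$seed))
  invisible(x)
}

# 3x3 stride-2 max pooling (16 -> 8 with ceiling), recording argmax indices.
maxpool_forward <- function(x) {
  d <- dim(x)  # h, w, C, B
  starts <- seq(1L, d[1] - 1L, by = 2L)
  ho <- length(starts)
  lin <- array(seq_len(prod(d)), d)
  out <- array(0, c(ho, ho, d[3], d[4]))
  idx <- array(0L, c(ho, ho, d[3], d[4]))
  nC <- d[3] * d[4]
  for (i in seq_len(ho)) for (j in seq_len(ho)) {
    rs <- starts[i]:min(starts[i] + 2L, d[1])
    cs <- starts[j]:min(starts[j] + 2L, d[2])
    sub <- matrix(x[rs, cs, , , drop = FALSE], length(rs) * length(cs), nC)
    li <- matrix(lin[rs, cs, , , drop = FALSE], length(rs) * length(cs), nC)
    am <- max.col(t(sub), ties.method = "first")
    sel <- cbind(am, seq_len(nC))
    out[i, j, , ] <- sub[sel]
    idx[i, j, , ] <- li[sel]
  }
  list(out = out, idx = idx, x_dim = d)
}

maxpool_backward <- function(dy, pool) {
  dx <- numeric(prod(pool$x_dim))
  ho <- dim(dy)[1]
  for (i in seq_len(ho)) for (j in seq_len(ho)) {
    ij <- as.vector(pool$idx[i, j, , ])
    dx[ij] <- dx[ij] + as.vector(dy[i, j, , ])
  }
  array(dx, pool$x_dim)
}

# Shared-branch forward; returns the 256 x B branch matrix and caches.
snn_branch_forward <- function(p, X) {
  B <- dim(X)[4]
  c1 <- conv_forward(X, p$W1, 11L, 5L, p$b1); a1 <- relu(c1$out)
  c2 <- conv_forward(a1, p$W2, 5L, 2L, p$b2); a2 <- relu(c2$out)
  pl <- maxpool_forward(a2)
  c3 <- conv_forward(pl$out, p$W3, 3L, 1L, p$b3); a3 <- relu(c3$out)
  f0 <- matrix(a3, ncol = B)
  z4 <- crossprod(p$Wf, f0) + p$bf
  a4 <- relu(z4)
  list(out = a4, X = X, c1 = c1, a1 = a1, c2 = c2, a2 = a2,
       pl = pl, c3 = c3, a3 = a3, f0 = f0, a4 = a4)
}

snn_branch_backward <- function(p, cache, da4) {
  da4 <- da4 * (cache$a4 > 0)
  dWf <- cache$f0 %*% t(da4)
  dbf <- rowSums(da4)
  df0 <- p$Wf %*% da4
  da3 <- array(df0, dim(cache$a3)) * (cache$a3 > 0)
  g3 <- conv_backward(da3, cache$c3$cols, p$W3, dim(cache$pl$out), 3L, 1L)
  da2 <- maxpool_backward(g3$dX, cache$pl) * (cache$a2 > 0)
  g2 <- conv_backward(da2, cache$c2$cols, p$W2, dim(cache$a1), 5L, 2L)
  da1 <- g2$dX * (cache$a1 > 0)
  g1 <- conv_backward(da1, cache$c1$cols, p$W1, dim(cache$X), 11L, 5L,
                      want_dx = FALSE)  # input layer: dX unused
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, Wf = dWf, bf = dbf)
}

softmax2 <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Raw head probabilities for (a, b) in that order: 2 x B matrix. The two
# patches are stacked into one branch batch of 2B (weight sharing makes this
# exact) and the branch outputs are split for the concatenating head.
snn_forward_pair <- function(model, a, b, keep_cache = FALSE) {
  p <- model$params
  B <- if (length(dim(a)) == 3L) dim(a)[3] else 1L
  X <- array(c(a, b), c(16L, 16L, 1L, 2L * B))
  cc <- snn_branch_forward(p, X)
  cat512 <- rbind(cc$out[, seq_len(B), drop = FALSE],
                  cc$out[, B + seq_len(B), drop = FALSE])
  probs <- softmax2(crossprod(p$Wh, cat512) + p$bh)
  if (keep_cache) list(probs = probs, cache = cc, cat512 = cat512, B = B)
  else probs
}

#' Symmetrised saliency score
#'
#' Probability that patch `a` is the more salient of the pair, evaluated in
#' both branch orders and averaged so that `score(a,b) = 1 - score(b,a)`
#' holds exactly.
#'
#' @param model An `snn_model`.
#' @param a,b 16 x 16 matrices or 16 x 16 x B arrays of patches.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
snn_score <- function(model, a, b) {
  p_ab <- snn_forward_pair(model, a, b)
  p_ba <- snn_forward_pair(model, b, a)
  as.numeric((p_ab[1, ] + p_ba[2, ]) / 2)
}

#' Synthetic saliency-discrimination patch pairs
#'
#' Generates textured 16 x 16 patches (oriented sinusoid gratings with mild
#' noise); in each pair one copy is degraded by Gaussian blur with
#' `sigma ~ U(blur_sigma)` and/or contrast scaling `~ U(contrast_range)`,
#' and the non-degraded patch is labelled salient. Pair order is randomised
#' with exactly balanced labels. Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param n Number of pairs (`n >= 2`).
#' @param blur_sigma Length-2 blur range, or `NULL` to disable blurring.
#' @param contrast_range Length-2 contrast-scale range, or `NULL` to
#'   disable contrast degradation. Disabling both is an error (there would
#'   be no signal to label).
#' @return Class `patch_pair_set`: arrays `a`, `b` (16 x 16 x n), integer
#'   `labels` (1 if `a` is the salient patch, else 0), and `seed`.
#' @export
make_patch_pairs <- function(seed, n, blur_sigma = c(1, 3),
                             contrast_range = c(0.2, 0.6)) {
  if (n < 2L) stop_medfuse("medfuse_param", "need n >= 2 pairs")
  if (is.null(blur_sigma) && is.null(contrast_range))
    stop_medfuse("medfuse_param",
                 "all degradations disabled: saliency labels would be undefined")
  modes <- c(if (!is.null(blur_sigma)) "blur",
             if (!is.null(contrast_range)) "contrast")
  if (length(modes) == 2L) modes <- c(modes, "both")
  cx <- matrix(rep(1:16, each = 16), 16, 16)
  cy <- matrix(rep(1:16, times = 16), 16, 16)
  with_seed(seed, {
    a <- array(0, c(16, 16, n)); b <- array(0, c(16, 16, n))
    labels <- integer(n)
    lab <- sample(rep(c(1L, 0L), length.out = n))  # exact balance
    for (i in seq_len(n)) {
      f <- stats::runif(1, 2, 6); th <- stats::runif(1, 0, pi)
      ph <- stats::runif(1, 0, 2 * pi)
      sharp <- clip01(0.5 + 0.35 * sin(2 * pi * f * (cx * cos(th) + cy * sin(th)) / 16 + ph) +
                        stats::rnorm(256, sd = 0.02))
      mode <- sample(modes, 1L)
      deg <- sharp
      if (mode %in% c("blur", "both"))
        deg <- gauss_blur(deg, stats::runif(1, blur_sigma[1], blur_sigma[2]))
      if (mode %in% c("contrast", "both")) {
        s <- stats::runif(1, contrast_range[1], contrast_range[2])
        deg <- mean(deg) + s * (deg - mean(deg))
      }
      deg <- clip01(deg)
      if (lab[i] == 1L) { a[, , i] <- sharp; b[, , i] <- deg }
      else              { a[, , i] <- deg;  b[, , i] <- sharp }
      labels[i] <- lab[i]
    }
    structure(list(a = a, b = b, labels = labels, seed = as.integer(seed)),
              class = "patch_pair_set")
  })
}

#' Train the Siamese network on a patch-pair set
#'
#' Minimises two-class cross-entropy with mini-batch SGD (momentum 0.9).
#' The data are split 80/20 into training and held-out validation by the
#' seed; held-out accuracy uses the symmetrised score.
#'
#' @param model An `snn_model`.
#' @param data A `patch_pair_set`.
#' @param epochs Training epochs.
#' @param learning_rate SGD learning rate.
#' @param seed Seed controlling the split and shuffling.
#' @param batch_size Mini-batch size.
#' @param verbose Print per-epoch loss.
#' @return Class `snn_fit`: `model` (trained), `accuracy` (held-out),
#'   `loss_history`, `n_train`, `n_valid`.
#' @export
train_snn <- function(model, data, epochs = 20L, learning_rate = 0.01,
                      seed = 1L, batch_size = 64L, verbose = FALSE) {
  stopifnot(inherits(model, "snn_model"), inherits(data, "patch_pair_set"))
  n <- length(data$labels)
  p <- model$params
  vel <- lapply(p, function(w) w * 0)
  with_seed(seed, {
    perm <- sample(n)
    n_tr <- floor(0.8 * n)
    tr <- perm[seq_len(n_tr)]; va <- perm[-seq_len(n_tr)]
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      losses <- c()
      for (start in seq(1L, length(ord), by = batch_size)) {
        ix <- ord[start:min(start + batch_size - 1L, length(ord))]
        B <- length(ix)
        fw <- snn_forward_pair(model, data$a[, , ix, drop = FALSE],
                               data$b[, , ix, drop = FALSE], keep_cache = TRUE)
        y1 <- data$labels[ix]
        probs <- fw$probs
        loss <- -mean(log(pmax(probs[cbind(2L - y1, seq_len(B))], 1e-12)))
        if (!is.finite(loss))
          stop_medfuse("medfuse_training",
                       sprintf("non-finite loss at epoch %d (learning_rate = %g)",
                               ep, learning_rate))
        losses <- c(losses, loss)
        dz <- probs
        dz[cbind(2L - y1, seq_len(B))] <- dz[cbind(2L - y1, seq_len(B))] - 1
        dz <- dz / B
        gWh <- fw$cat512 %*% t(dz)
        gbh <- rowSums(dz)
        dcat <- model$params$Wh %*% dz
        dstack <- cbind(dcat[1:256, , drop = FALSE], dcat[257:512, , drop = FALSE])
        grads <- snn_branch_backward(model$params, fw$cache, dstack)
        grads$Wh <- gWh; grads$bh <- gbh
        for (nm in names(grads)) {
          vel[[nm]] <- 0.9 * vel[[nm]] - learning_rate * grads[[nm]]
          model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
        }
      }
      history[ep] <- mean(losses)
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
    }
    s <- snn_score(model, data$a[, , va, drop = FALSE], data$b[, , va, drop = FALSE])
    acc <- mean((s > 0.5) == (data$labels[va] == 1L))
    structure(list(model = model, accuracy = acc, loss_history = history,
                   n_train = length(tr), n_valid = length(va)),
              class = "snn_fit")
  })
}

#' @export
print.snn_fit <- function(x, ...) {
  cat(sprintf("<snn_fit> held-out accuracy %.3f (%d train / %d validation)\n",
              x$accuracy, x$n_train, x$n_valid))
  cat(sprintf("  final training loss %.4f over %d epochs\n",
              x$loss_history[length(x$loss_history)], length(x$loss_history)))
  invisible(x)
}

#' Dense Siamese weight map over an image pair
#'
#' Slides 16 x 16 windows at the given stride (final windows are anchored to
#' the far edge so every pixel is covered), scores each window with the
#' symmetrised network score for source 1, accumulates the score over all
#' windows covering each pixel and divides by the coverage count.
#'
#' @param img1,img2 `image_plane`s or matrices of one shape, at least 16 x 16.
#' @param model A trained `snn_model` (or an `snn_fit`).
#' @param stride Window stride in pixels, 1..16 (stride 1 is exact; the
#'   default 2 is four times faster with near-identical maps).
#' @return Matrix of per-pixel weights for source 1, entries in \[0, 1\],
#'   same shape as the inputs.
#' @export
snn_weight_map <- function(img1, img2, model, stride = 2L) {
  if (inherits(model, "snn_fit")) model <- model$model
  m1 <- px(img1); m2 <- px(img2)
  if (!all(dim(m1) == dim(m2)))
    stop_medfuse("medfuse_validation", "images must share one shape")
  h <- nrow(m1); w <- ncol(m1)
  if (h < 16L || w < 16L)
    stop_medfuse("medfuse_validation", "images must be at least 16x16")
  if (stride < 1L || stride > 16L)
    stop_medfuse("medfuse_param", "stride must be in 1..16 (larger leaves uncovered pixels)")
  starts <- function(nn) unique(c(seq(1L, nn - 15L, by = stride), nn - 15L))
  sr <- starts(h); sc <- starts(w)
  wins <- expand.grid(r = sr, c = sc)
  nw <- nrow(wins)
  W <- matrix(0, h, w); cnt <- matrix(0, h, w)
  chunk <- 64L
  for (s0 in seq(1L, nw, by = chunk)) {
    ix <- s0:min(s0 + chunk - 1L, nw)
    pa <- array(0, c(16, 16, length(ix))); pb <- pa
    for (j in seq_along(ix)) {
      r <- wins$r[ix[j]]; cc <- wins$c[ix[j]]
      pa[, , j] <- m1[r:(r + 15L), cc:(cc + 15L)]
      pb[, , j] <- m2[r:(r + 15L), cc:(cc + 15L)]
    }
    s <- snn_score(model, pa, pb)
    for (j in seq_along(ix)) {
      r <- wins$r[ix[j]]; cc <- wins$c[ix[j]]
      W[r:(r + 15L), cc:(cc + 15L)] <- W[r:(r + 15L), cc:(cc + 15L)] + s[j]
      cnt[r:(r + 15L), cc:(cc + 15L)] <- cnt[r:(r + 15L), cc:(cc + 15L)] + 1
    }
  }
  W / cnt
}

#' Save / load a Siamese model
#'
#' The spec (layer schedule, seed) is embedded alongside the parameters for
#' reproducibility.
#'
#' @param model An `snn_model` or `snn_fit`.
#' @param path File path (RDS).
#' @return `snn_save`: `path`, invisibly. `snn_load`: an `snn_model`.
#' @export
snn_save <- function(model, path) {
  if (inherits(model, "snn_fit")) model <- model$model
  stopifnot(inherits(model, "snn_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname snn_save
#' @export
snn_load <- function(path) {
  if (!file.exists(path))
    stop_medfuse("medfuse_param", sprintf("no model file at '%s'", path))
  obj <- readRDS(path)
  if (!all(c("params", "spec") %in% names(obj)))
    stop_medfuse("medfuse_format", "file does not contain a saved Siamese model")
  structure(obj, class = "snn_model")
}
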