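#' Detail-content fusion by multi-layer deep-feature activity
#'
#' The detail branch turns each source's four-level [feature_stack][extract_features]
#' into per-pixel weights and blends the source detail parts:
#'
#' 1. *Activity map*: at each level the L1 norm across feature channels,
#'    `C(x,y) = sum_n |phi^{i,n}(x,y)|`.
#' 2. *Block average* with radius `r` (default 1): a zero-padded box filter
#'    `(2r+1)^2` window, which makes the weights robust to slight
#'    misregistration (out-of-frame terms contribute zero, so corner values
#'    are attenuated rather than renormalised).
#' 3. *Softmax weights* across the K sources,
#'    `w_k = c_k / sum_n c_n`; where all activities vanish each source
#'    receives `1/K`.
#' 4. *Upsampling* by block replication: each level-`i` weight fills its
#'    `2^(i-1) x 2^(i-1)` block, cropped to the detail size, which preserves
#'    the per-pixel sum-to-1 property exactly.
#' 5. *Per-level fusion* `F_d^i = sum_k w_k^i . I_k^d`, then the pointwise
#'    maximum across the four levels gives the fused detail `F_d`.
#'
#' @name detail_fusion
NULL

#' L1-norm activity map of one feature level
#'
#' @param level A feature level: array H x W x C.
#' @return Non-negative matrix H x W.
#' @export
activity_map <- function(level) {
  d <- dim(level)
  if (is.null(d) || length(d) != 3L || any(d == 0L))
    stop_medfuse("medfuse_validation", "level must be a non-empty H x W x C array")
  matrix(rowSums(abs(matrix(level, d[1] * d[2], d[3]))), d[1], d[2])
}

#' Block-averaged activity map
#'
#' `(2r+1)^2` box window, zero padding, literal `1/(2r+1)^2` normalisation
#' everywhere (so border values are attenuated, e.g. a corner keeps 4/9 of a
#' constant map at r = 1).
#'
#' @param C Non-negative activity matrix.
#' @param r Block radius, `r >= 0`; `r = 0` returns `C` unchanged.
#' @return Matrix of the same shape.
#' @export
block_average <- function(C, r = 1L) {
  if (r < 0) stop_medfuse("medfuse_param", "r must be a non-negative integer")
  r <- as.integer(r)
  if (r == 0L) return(C)
  h <- nrow(C); w <- ncol(C)
  acc <- matrix(0, h, w)
  for (b in -r:r) for (th in -r:r) {
    rs <- seq_len(h) + b
    cs <- seq_len(w) + th
    ok_r <- rs >= 1L & rs <= h
    ok_c <- cs >= 1L & cs <= w
    acc[ok_r, ok_c] <- acc[ok_r, ok_c] + C[rs[ok_r], cs[ok_c], drop = FALSE]
  }
  acc / (2 * r + 1)^2
}

#' Softmax weight maps from K activity maps
#'
#' @param finals List of K non-negative activity matrices of one shape.
#' @return List of K weight matrices summing to 1 at every pixel; pixels
#'   where every activity is zero receive uniform `1/K`.
#' @export
softmax_weights <- function(finals) {
  K <- length(finals)
  if (K < 1L) stop_medfuse("medfuse_validation", "need at least one activity map")
  d <- dim(finals[[1]])
  for (f in finals) {
    if (!all(dim(f) == d))
      stop_medfuse("medfuse_validation", "activity maps must share one shape")
    if (min(f) < 0)
      stop_medfuse("medfuse_validation", "activity maps must be non-negative")
  }
  denom <- Reduce(`+`, finals)
  zero <- denom == 0
  denom[zero] <- 1
  w <- lapply(finals, function(f) {
    wk <- f / denom
    wk[zero] <- 1 / K
    wk
  })
  if (K == 2L) {
    # Give the larger-activity source the exact complement of the smaller's
    # quotient: sums are then exactly 1 at every pixel while swap symmetry
    # is preserved (at ties the quotient c/(2c) = 0.5 is already exact).
    first_small <- finals[[1]] <= finals[[2]]
    w1 <- ifelse(first_small, w[[1]], 1 - w[[2]])
    w2 <- ifelse(first_small, 1 - w[[1]], w[[2]])
    w1[zero] <- 0.5; w2[zero] <- 0.5
    w <- list(w1, w2)
  }
  w
}

#' Upsample a level-resolution weight map by block replication
#'
#' Each value fills its `2^(i-1) x 2^(i-1)` block and the result is cropped
#' to `target`; no interpolation is applied, so sum-to-1 across sources is
#' preserved exactly.
#'
#' @param w Weight matrix at level-`i` resolution.
#' @param target Integer vector `c(H, W)` of the detail size.
#' @param level Level index i in 1..4 (block size `2^(i-1)`).
#' @return H x W matrix.
#' @export
upsample_weights <- function(w, target, level) {
  f <- 2L^(as.integer(level) - 1L)
  if (nrow(w) != ceiling(target[1] / f) || ncol(w) != ceiling(target[2] / f))
    stop_medfuse("medfuse_param",
                 sprintf("target %dx%d incompatible with a level-%d map of %dx%d",
                         target[1], target[2], level, nrow(w), ncol(w)))
  w[rep(seq_len(nrow(w)), each = f)[seq_len(target[1])],
    rep(seq_len(ncol(w)), each = f)[seq_len(target[2])], drop = FALSE]
}

#' Fuse detail parts under full-resolution weight maps
#'
#' @param details List of K detail matrices.
#' @param weight_maps List of 4 levels, each a list of K full-resolution
#'   weight matrices.
#' @return Class `detail_fusion`: `per_level` (four fused detail matrices)
#'   and `combined` (their pointwise maximum).
#' @export
fuse_detail_contents <- function(details, weight_maps) {
  d <- dim(details[[1]])
  for (m in details) if (!all(dim(m) == d))
    stop_medfuse("medfuse_validation", "detail matrices must share one shape")
  per_level <- lapply(weight_maps, function(wl) {
    if (length(wl) != length(details))
      stop_medfuse("medfuse_validation", "one weight map per source is required")
    acc <- matrix(0, d[1], d[2])
    for (k in seq_along(details)) {
      if (!all(dim(wl[[k]]) == d))
        stop_medfuse("medfuse_validation", "weight map shape must match the details")
      acc <- acc + wl[[k]] * details[[k]]
    }
    acc
  })
  structure(list(per_level = per_level,
                 combined = Reduce(pmax, per_level)),
            class = "detail_fusion")
}

#' Run the whole detail-fusion branch
#'
#' Convenience wrapper: activity maps, block averaging, softmax weights,
#' block-replication upsampling and per-level fusion with the cross-level
#' maximum, for K sources.
#'
#' @param details List of K detail matrices.
#' @param stacks List of K `feature_stack`s (one per source).
#' @param r Block-average radius.
#' @return A `detail_fusion` object; the fused detail is `$combined`.
#' @export
detail_fuse <- function(details, stacks, r = 1L) {
  target <- dim(details[[1]])
  weight_maps <- lapply(1:4, function(i) {
    finals <- lapply(stacks, function(s)
      block_average(activity_map(s$levels[[i]]), r))
    lapply(softmax_weights(finals), upsample_weights, target = target, level = i)
  })
  fuse_detail_contents(details, weight_maps)
}
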