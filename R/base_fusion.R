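#' Fuse two base parts by a weighted sum
#'
#' `F_b = alpha1 * I1_b + alpha2 * I2_b` with fixed scalars (default
#' 0.5/0.5, which preserves the features common to both sources), or
#' `F_b = W . I1_b + (1 - W) . I2_b` with a per-pixel weight map `W` in
#' \[0, 1\] — typically the Siamese saliency map from [snn_weight_map()].
#' Either way the output is a convex combination, so it stays within the
#' pointwise range of the inputs (and in \[0, 1\]).
#'
#' @param base1,base2 Base-part matrices (or `image_plane`s) of one shape.
#' @param mode `"scalar"` or `"snn"`.
#' @param alpha Length-2 weights summing to 1 (scalar mode).
#' @param weight_map Per-pixel weights for source 1 (snn mode), entries in
#'   \[0, 1\], same shape as the base parts.
#' @return Fused base matrix.
#' @export
fuse_base <- function(base1, base2, mode = c("scalar", "snn"),
                      alpha = c(0.5, 0.5), weight_map = NULL) {
  mode <- match.arg(mode)
  b1 <- px(base1); b2 <- px(base2)
  if (!all(dim(b1) == dim(b2)))
    stop_medfuse("medfuse_validation", "base parts must share one shape")
  if (mode == "scalar") {
    if (length(alpha) != 2L || any(alpha < 0) || any(alpha > 1) ||
        abs(sum(alpha) - 1) > 1e-9)
      stop_medfuse("medfuse_param", "alpha must be two weights in [0,1] summing to 1")
    alpha[1] * b1 + alpha[2] * b2
  } else {
    if (is.null(weight_map))
      stop_medfuse("medfuse_param", "snn mode requires a weight_map")
    W <- px(weight_map)
    if (!all(dim(W) == dim(b1)))
      stop_medfuse("medfuse_validation", "weight_map shape must match the base parts")
    if (min(W) < 0 || max(W) > 1)
      stop_medfuse("medfuse_validation", "weight_map entries must lie in [0,1]")
    W * b1 + (1 - W) * b2
  }
}
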