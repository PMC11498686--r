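#' @name preprocess
#' @title Optional pre-processing: rigid registration, anisotropic diffusion,
#'   histogram equalisation
#' @description
#' The fusion pipeline assumes pre-registered sources; these stages are
#' provided for inputs that need alignment or enhancement first and are all
#' off by default in [fusion_config()].
NULL

# Bilinear resampling of `img` under a rigid transform: content is shifted by
# (dx, dy) pixels (dx = columns/x, dy = rows/y) and rotated by theta degrees
# about the image centre. Samples falling outside the frame read as zero.
apply_rigid <- function(img, dx = 0, dy = 0, theta = 0) {
  m <- px(img)
  h <- nrow(m); w <- ncol(m)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  th <- theta * pi / 180
  cs <- cos(th); sn <- sin(th)
  gc <- matrix(rep(seq_len(w), each = h), h, w)
  gr <- matrix(rep(seq_len(h), times = w), h, w)
  # inverse map: undo shift, then undo rotation about centre
  xc <- gc - cx - dx
  yc <- gr - cy - dy
  sx <- cs * xc + sn * yc + cx
  sy <- -sn * xc + cs * yc + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  at <- function(r, c) {
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    v <- numeric(length(r))
    v[ok] <- m[cbind(r[ok], c[ok])]
    v
  }
  v <- (1 - fy) * ((1 - fx) * at(y0, x0) + fx * at(y0, x0 + 1)) +
       fy * ((1 - fx) * at(y0 + 1, x0) + fx * at(y0 + 1, x0 + 1))
  matrix(v, h, w)
}

ssd_cost <- function(a, b) sum((a - b)^2)

# Mutual information over a joint histogram with Laplace (+1) smoothing.
mi_cost <- function(a, b, bins = 64L) {
  ia <- pmin(pmax(floor(a * bins) + 1L, 1L), bins)
  ib <- pmin(pmax(floor(b * bins) + 1L, 1L), bins)
  joint <- matrix(1, bins, bins)  # Laplace smoothing
  tab <- table(factor(ia, levels = 1:bins), factor(ib, levels = 1:bins))
  joint <- joint + as.matrix(tab)
  p <- joint / sum(joint)
  pa <- rowSums(p); pb <- colSums(p)
  sum(p * log(p / outer(pa, pb)))
}

#' Rigid intensity-based registration
#'
#' Aligns `moving` to `fixed` with a translation + rotation found by
#' exhaustive integer grid search over the stated bounds followed by
#' coordinate-descent refinement (successive 1-D line searches on dx, dy,
#' theta). The cost is either the sum of squared differences (minimised) or
#' mutual information over a 64-bin smoothed joint histogram (maximised).
#'
#' @param moving,fixed `image_plane`s (or matrices) of identical shape.
#' @param cost `"ssd"` or `"mi"`.
#' @param search List with elements `dx`, `dy` (integer pixel bounds,
#'   length-2) and optionally `theta` (degree bounds, searched in 1-degree
#'   steps). Default `+/-5` px, no rotation.
#' @param refine Run the sub-pixel local refinement after the grid search.
#' @return List with `image` (resampled moving image, an `image_plane`) and
#'   `transform` (class `rigid_transform`: `dx`, `dy`, `theta`, `cost_name`,
#'   `cost_value`).
#' @export
register_rigid <- function(moving, fixed, cost = c("ssd", "mi"),
                           search = list(dx = c(-5, 5), dy = c(-5, 5)),
                           refine = TRUE) {
  cost <- match.arg(cost)
  mv <- px(moving); fx <- px(fixed)
  if (!all(dim(mv) == dim(fx)))
    stop_medfuse("medfuse_validation", "moving and fixed images must share one shape")
  if (!all(is.finite(unlist(search))))
    stop_medfuse("medfuse_param", "search bounds must be finite")
  if (cost == "mi" && max(fx) - min(fx) < .Machine$double.eps)
    stop_medfuse("medfuse_degenerate",
                 "fixed image is constant: mutual information is undefined up to ties")
  sgn <- if (cost == "ssd") 1 else -1  # minimise signed cost
  eval_cost <- function(p) {
    w <- apply_rigid(mv, p[1], p[2], p[3])
    sgn * (if (cost == "ssd") ssd_cost(w, fx) else mi_cost(w, fx))
  }
  dxs <- seq(ceiling(search$dx[1]), floor(search$dx[2]))
  dys <- seq(ceiling(search$dy[1]), floor(search$dy[2]))
  ths <- if (is.null(search$theta)) 0 else
    seq(ceiling(search$theta[1]), floor(search$theta[2]))
  grid <- expand.grid(dx = dxs, dy = dys, theta = ths)
  costs <- apply(grid, 1L, eval_cost)
  best <- as.numeric(grid[which.min(costs), ])
  bestc <- min(costs)
  if (refine) {
    for (sweep in 1:3) {
      for (i in 1:3) {
        if (i == 3L && is.null(search$theta)) next
        f1 <- function(v) { p <- best; p[i] <- v; eval_cost(p) }
        o <- stats::optimize(f1, lower = best[i] - 1, upper = best[i] + 1, tol = 1e-3)
        if (o$objective < bestc) { best[i] <- o$minimum; bestc <- o$objective }
      }
    }
  }
  out <- apply_rigid(mv, best[1], best[2], best[3])
  tr <- structure(list(dx = best[1], dy = best[2], theta = best[3],
                       cost_name = cost, cost_value = sgn * bestc),
                  class = "rigid_transform")
  list(image = image_plane(clip01(out),
                           bit_depth = if (inherits(moving, "image_plane"))
                             moving$source_bit_depth else 8L),
       transform = tr)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> dx=%.3f dy=%.3f theta=%.3f deg, %s=%.6g\n",
              x$dx, x$dy, x$theta, toupper(x$cost_name), x$cost_value))
  invisible(x)
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing with the exponential conductance
#' `g(d) = exp(-(d/kappa)^2)` over the 4-neighbourhood, Neumann
#' (replicated) borders. The output is clipped to \[0, 1\].
#'
#' @param img `image_plane` or matrix.
#' @param iterations Number of diffusion steps; 0 returns the input.
#' @param kappa Conductance scale: gradients well below `kappa` diffuse
#'   freely, gradients above it are preserved.
#' @param dt Time step in (0, 0.25] for stability.
#' @return Same type as `img`.
#' @export
anisodiffuse <- function(img, iterations = 10L, kappa = 0.1, dt = 0.2) {
  if (iterations < 0 || kappa <= 0 || dt <= 0 || dt > 0.25)
    stop_medfuse("medfuse_param",
                 "need iterations >= 0, kappa > 0 and dt in (0, 0.25]")
  m <- px(img)
  h <- nrow(m); w <- ncol(m)
  for (it in seq_len(iterations)) {
    dN <- rbind(m[1, , drop = FALSE], m[-h, , drop = FALSE]) - m
    dS <- rbind(m[-1, , drop = FALSE], m[h, , drop = FALSE]) - m
    dW <- cbind(m[, 1, drop = FALSE], m[, -w, drop = FALSE]) - m
    dE <- cbind(m[, -1, drop = FALSE], m[, w, drop = FALSE]) - m
    m <- m + dt * (exp(-(dN / kappa)^2) * dN + exp(-(dS / kappa)^2) * dS +
                   exp(-(dW / kappa)^2) * dW + exp(-(dE / kappa)^2) * dE)
  }
  m <- clip01(m)
  if (inherits(img, "image_plane")) image_plane(m, img$source_bit_depth, img$meta) else m
}

#' Histogram equalisation
#'
#' Classical CDF remapping on 256 intensity bins. A constant image is
#' returned unchanged (its histogram is degenerate).
#'
#' @param img `image_plane` or matrix in \[0, 1\].
#' @return Same type as `img`, intensities in \[0, 1\].
#' @export
hist_equalize <- function(img) {
  m <- px(img)
  if (max(m) - min(m) < .Machine$double.eps) return(img)
  lev <- pmin(pmax(as.integer(round(m * 255)), 0L), 255L)
  cdf <- cumsum(tabulate(lev + 1L, nbins = 256L)) / length(lev)
  out <- matrix(cdf[lev + 1L], nrow(m), ncol(m))
  if (inherits(img, "image_plane")) image_plane(out, img$source_bit_depth, img$meta) else out
}
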