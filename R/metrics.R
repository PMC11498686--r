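#' Fusion quality metrics
#'
#' The evaluation suite computes, on the 0-255 intensity scale (so values
#' are commensurate with the image-fusion literature): mean squared error,
#' peak signal-to-noise ratio, the structural similarity index, the
#' (normalised) mutual-information fusion metric Q_MI, and a multi-scale
#' edge-preservation score Q_M. [fusion_metrics()] assembles all five for a
#' fused image against its two sources, together with a record of the
#' formula conventions used.
#'
#' @name metrics
NULL

#' Mean squared error (0-255 scale)
#'
#' @param a,b `image_plane`s or matrices in \[0, 1\] of one shape.
#' @return Mean over pixels of the squared difference of 0-255 intensities.
#' @export
mse <- function(a, b) {
  ma <- px(a); mb <- px(b)
  if (!all(dim(ma) == dim(mb)))
    stop_medfuse("medfuse_validation", "images must share one shape")
  mean((255 * (ma - mb))^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(255^2 / MSE)` in dB; identical images give `Inf`.
#'
#' @inheritParams mse
#' @return PSNR in dB (`Inf` when MSE is zero).
#' @export
psnr <- function(a, b) {
  m <- mse(a, b)
  if (m == 0) Inf else 10 * log10(255^2 / m)
}

# Separable valid-mode filtering with an odd symmetric 1-D kernel.
filter_valid <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  fd <- function(m) {
    n <- nrow(m) - 2L * r
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[(j - 1L) + seq_len(n), , drop = FALSE]
    out
  }
  t(fd(t(fd(x))))
}

#' Structural similarity index
#'
#' The standard formulation: 11 x 11 Gaussian window with sigma 1.5,
#' stabilisers `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with `L = 255`, local
#' map averaged over the valid region. Symmetric in its arguments;
#' `ssim(I, I) = 1` exactly.
#'
#' @inheritParams mse
#' @return SSIM in \[-1, 1\].
#' @export
ssim <- function(a, b) {
  ma <- 255 * px(a); mb <- 255 * px(b)
  if (!all(dim(ma) == dim(mb)))
    stop_medfuse("medfuse_validation", "images must share one shape")
  if (min(dim(ma)) < 11L)
    stop_medfuse("medfuse_param", "images must be at least 11x11 for the SSIM window")
  k <- exp(-((-5:5)^2) / (2 * 1.5^2)); k <- k / sum(k)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  mu_a <- filter_valid(ma, k); mu_b <- filter_valid(mb, k)
  s_aa <- filter_valid(ma * ma, k) - mu_a * mu_a
  s_bb <- filter_valid(mb * mb, k) - mu_b * mu_b
  s_ab <- filter_valid(ma * mb, k) - mu_a * mu_b
  mean(((2 * mu_a * mu_b + C1) * (2 * s_ab + C2)) /
         ((mu_a * mu_a + mu_b * mu_b + C1) * (s_aa + s_bb + C2)))
}

# Marginal/joint entropies in bits from 256-bin histograms.
hist256 <- function(x) pmin(pmax(as.integer(round(px(x) * 255)), 0L), 255L)

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

mi_bits <- function(ia, ib) {
  joint <- table(factor(ia, levels = 0:255), factor(ib, levels = 0:255))
  ha <- entropy_bits(tabulate(ia + 1L, 256L))
  hb <- entropy_bits(tabulate(ib + 1L, 256L))
  hab <- entropy_bits(as.vector(joint))
  ha + hb - hab
}

#' Mutual-information fusion metric Q_MI
#'
#' With `normalized = FALSE` this is `MI(A, F) + MI(B, F)` from 256-bin
#' joint histograms (entropies in bits). The default normalised variant is
#' `2 [ MI(A,F) / (H(A) + H(F)) + MI(B,F) / (H(B) + H(F)) ]`, which equals
#' 2 when `F = A = B` and is robust to the sources' absolute entropies.
#'
#' @param a,b Source images.
#' @param f Fused image.
#' @param normalized Use the normalised variant (default).
#' @return Non-negative score.
#' @export
q_mi <- function(a, b, f, normalized = TRUE) {
  ia <- hist256(a); ib <- hist256(b); i_f <- hist256(f)
  if (length(ia) != length(i_f) || length(ib) != length(i_f))
    stop_medfuse("medfuse_validation", "images must share one shape")
  ha <- entropy_bits(tabulate(ia + 1L, 256L))
  hb <- entropy_bits(tabulate(ib + 1L, 256L))
  hf <- entropy_bits(tabulate(i_f + 1L, 256L))
  if (normalized && hf == 0)
    stop_medfuse("medfuse_degenerate",
                 "fused image is constant: normalised Q_MI has a zero denominator")
  m_af <- mi_bits(ia, i_f); m_bf <- mi_bits(ib, i_f)
  if (normalized) 2 * (m_af / (ha + hf) + m_bf / (hb + hf))
  else m_af + m_bf
}

#' Multi-scale edge-preservation score Q_M
#'
#' Decomposes both sources and the fused image with the dual-tree complex
#' wavelet transform and measures, at every level and oriented highpass
#' subband, how well each source's edge magnitude survives into the fused
#' image: per coefficient the preservation `min(|F|,|A_k|)/max(|F|,|A_k|)`
#' (1 where both vanish), weighted by the source magnitude `|A_k|`, summed
#' over both sources and averaged over levels. 1 when the fused image
#' equals both sources; near 0 when its edges are destroyed.
#'
#' @param a,b Source images.
#' @param f Fused image.
#' @param levels Decomposition depth (image sides must be at least
#'   `2^levels`).
#' @return Score in \[0, 1\].
#' @export
q_m <- function(a, b, f, levels = 3L) {
  ma <- px(a); mb <- px(b); mf <- px(f)
  if (!all(dim(ma) == dim(mf)) || !all(dim(mb) == dim(mf)))
    stop_medfuse("medfuse_validation", "images must share one shape")
  fa <- dtcwt_forward(ma, levels)
  fb <- dtcwt_forward(mb, levels)
  ff <- dtcwt_forward(mf, levels)
  lev_scores <- numeric(levels)
  for (l in seq_len(levels)) {
    num <- 0; den <- 0
    for (o in 1:6) {
      Fm <- Mod(ff$highpass[[l]][[o]])
      for (src in list(fa, fb)) {
        Am <- Mod(src$highpass[[l]][[o]])
        hi <- pmax(Fm, Am)
        p <- ifelse(hi == 0, 1, pmin(Fm, Am) / ifelse(hi == 0, 1, hi))
        num <- num + sum(Am * p)
        den <- den + sum(Am)
      }
    }
    lev_scores[l] <- if (den == 0) 1 else num / den
  }
  mean(lev_scores)
}

#' Full metric report for a fused image
#'
#' MSE and PSNR are reported against each source and as their mean (the
#' fused image is not expected to equal either source, so both views are
#' informative); SSIM is the mean of the per-source values; Q_MI and Q_M
#' are intrinsically two-source metrics.
#'
#' @param a,b Source images.
#' @param f Fused image.
#' @param qmi_normalized Passed to [q_mi()].
#' @param qm_levels Passed to [q_m()].
#' @return Class `metric_report`.
#' @export
fusion_metrics <- function(a, b, f, qmi_normalized = TRUE, qm_levels = 3L) {
  rep <- list(
    mse = list(a = mse(a, f), b = mse(b, f)),
    psnr = list(a = psnr(a, f), b = psnr(b, f)),
    ssim = list(a = ssim(a, f), b = ssim(b, f)),
    q_mi = q_mi(a, b, f, normalized = qmi_normalized),
    q_m = q_m(a, b, f, levels = qm_levels),
    conventions = list(
      scale = "0-255",
      mse = "mean over pixels of squared difference, per source + mean",
      psnr = "10*log10(255^2/MSE); Inf at MSE = 0",
      ssim = "11x11 Gaussian sigma 1.5, C1=(0.01*255)^2, C2=(0.03*255)^2",
      q_mi = if (qmi_normalized)
        "2*[MI(A,F)/(H(A)+H(F)) + MI(B,F)/(H(B)+H(F))], 256 bins, bits"
      else "MI(A,F)+MI(B,F), 256 bins, bits",
      q_m = sprintf("dual-tree wavelet edge preservation, %d levels (package-defined variant)",
                    qm_levels)
    )
  )
  rep$mse$mean <- (rep$mse$a + rep$mse$b) / 2
  rep$psnr$mean <- (rep$psnr$a + rep$psnr$b) / 2
  rep$ssim$mean <- (rep$ssim$a + rep$ssim$b) / 2
  structure(rep, class = "metric_report")
}

#' Flatten a metric report to a named record
#'
#' @param x A `metric_report`.
#' @return Named list of scalars plus the conventions block, suitable for
#'   JSON/YAML serialisation.
#' @export
as_record <- function(x) UseMethod("as_record")

#' @export
as_record.metric_report <- function(x) {
  list(mse_a = x$mse$a, mse_b = x$mse$b, mse_mean = x$mse$mean,
       psnr_a = x$psnr$a, psnr_b = x$psnr$b, psnr_mean = x$psnr$mean,
       ssim_a = x$ssim$a, ssim_b = x$ssim$b, ssim_mean = x$ssim$mean,
       q_mi = x$q_mi, q_m = x$q_m, conventions = x$conventions)
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report> (0-255 scale)\n")
  cat(sprintf("  MSE : a %.3f | b %.3f | mean %.3f\n", x$mse$a, x$mse$b, x$mse$mean))
  cat(sprintf("  PSNR: a %.2f | b %.2f | mean %.2f dB\n", x$psnr$a, x$psnr$b, x$psnr$mean))
  cat(sprintf("  SSIM: a %.4f | b %.4f | mean %.4f\n", x$ssim$a, x$ssim$b, x$ssim$mean))
  cat(sprintf("  Q_MI: %.4f   Q_M: %.4f\n", x$q_mi, x$q_m))
  invisible(x)
}
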