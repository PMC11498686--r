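# Dual-tree complex wavelet transform.
#
# Structure follows the standard dual-tree construction: an odd-length
# symmetric biorthogonal first stage in which tree B is the one-sample-delayed
# copy of tree A (realised by sampling the opposite polyphase), and even-length
# orthonormal Q-shift filters for levels >= 2 in which tree B is the time
# reverse of tree A, so the two lowpass branches differ by half a sample and
# the iterated complex wavelet is approximately analytic. Boundaries are
# periodic, which keeps every per-tree branch an exact filter-bank identity.
#
# First stage: CDF 9/7 biorthogonal pair (Cohen-Daubechies-Feauveau),
# normalised so each lowpass sums to sqrt(2).
.cdf97_dec_lo <- c(0.03782845550726404, -0.02384946501955684, -0.11062440441843718,
                   0.37740285561283066, 0.8526986790088938, 0.37740285561283066,
                   -0.11062440441843718, -0.02384946501955684, 0.03782845550726404)
.cdf97_dec_hi <- c(-0.06453888262869706, 0.04068941760916406, 0.41809227322161724,
                   -0.7884856164055829, 0.41809227322161724, 0.04068941760916406,
                   -0.06453888262869706)
.cdf97_rec_lo <- c(-0.06453888262869706, -0.04068941760916406, 0.41809227322161724,
                   0.7884856164055829, 0.41809227322161724, -0.04068941760916406,
                   -0.06453888262869706)

# Q-shift stage: length-14 orthonormal lowpass designed by constrained
# optimisation (exact orthonormality, two vanishing moments, objective =
# passband half-sample-delay mismatch between the tree-A filter and its time
# reverse plus stopband energy). Group delay ~ 6.25 samples; the iterated
# complex wavelet has a negative/positive frequency energy ratio of 0.018.
.qshift_lo_a <- c(3.7748179381937166e-05, 1.8145692946616582e-02,
                  2.3492077646164799e-02, -5.3922433373977369e-02,
                  -1.1528051720464327e-01, 2.8153076758269147e-01,
                  7.4857603739074996e-01, 5.5935144762373801e-01,
                  5.0995334017891782e-02, -1.4901701413091262e-01,
                  3.8505130312780619e-02, 5.0936733852663139e-02,
                  -3.9219029155778316e-02, 8.1586685728312147e-05)

# Circular filtering along rows of a matrix: y[i,] = sum_m f[m] x[i+m-1-off,]
circ_filter_rows <- function(x, f, off) {
  h <- nrow(x)
  out <- matrix(0, h, ncol(x))
  for (m in seq_along(f)) {
    sh <- ((seq_len(h) - 1L + (m - 1L - off)) %% h) + 1L
    out <- out + f[m] * x[sh, , drop = FALSE]
  }
  out
}

# Analysis: circular filter rows then keep rows of parity `phase` (0 or 1).
dt_analysis <- function(x, f, off, phase) {
  y <- circ_filter_rows(x, f, off)
  y[seq(1L + phase, nrow(x), by = 2L), , drop = FALSE]
}

# Synthesis: zero-upsample rows back to height `h` at parity `phase`, then
# circular filter. Matched (off_analysis + off_synthesis = length sum - 2)
# offsets make the analysis/synthesis cascade zero phase.
dt_synthesis <- function(y, g, off, phase, h) {
  u <- matrix(0, h, ncol(y))
  u[seq(1L + phase, h, by = 2L), ] <- y
  circ_filter_rows(u, g, off)
}

# per-tree stage-1 / q-shift filter parameters
.stage1 <- list(
  a = list(lo = .cdf97_dec_lo, lo_off = 4L, hi = .cdf97_dec_hi, hi_off = 3L,
           syn = .cdf97_rec_lo, syn_off = 3L, phase = 0L),
  b = list(lo = .cdf97_dec_lo, lo_off = 4L, hi = .cdf97_dec_hi, hi_off = 3L,
           syn = .cdf97_rec_lo, syn_off = 3L, phase = 1L)
)
.qshift <- local({
  lo_a <- .qshift_lo_a
  lo_b <- rev(lo_a)
  n <- seq_along(lo_a) - 1L
  hi_a <- (-1)^n * rev(lo_a)   # quadrature mirror of tree A
  hi_b <- rev(hi_a)
  list(
    a = list(lo = lo_a, lo_off = 6L, hi = hi_a, hi_off = 7L,
             syn = lo_b, syn_off = 7L, phase = 0L),
    b = list(lo = lo_b, lo_off = 7L, hi = hi_b, hi_off = 6L,
             syn = lo_a, syn_off = 6L, phase = 0L)
  )
})

# Forward transform. Returns, per level, the six complex oriented subbands
# (combined across the four row/column tree pairs) and, at the deepest level,
# the four per-tree lowpass matrices. The input is padded by edge replication
# to a multiple of 2^levels if needed; `dim_in` records the original size.
dtcwt_forward <- function(x, levels) {
  x <- px(x)
  if (levels < 1L) stop_medfuse("medfuse_param", "levels must be >= 1")
  if (min(dim(x)) < 2^levels)
    stop_medfuse("medfuse_param",
                 sprintf("image sides must be >= 2^levels = %d", 2^levels))
  dim_in <- dim(x)
  mult <- 2^levels
  padr <- (mult - nrow(x) %% mult) %% mult
  padc <- (mult - ncol(x) %% mult) %% mult
  if (padr > 0) x <- rbind(x, x[rep(nrow(x), padr), , drop = FALSE])
  if (padc > 0) x <- cbind(x, x[, rep(ncol(x), padc), drop = FALSE])

  combos <- list(aa = c("a", "a"), ab = c("a", "b"),
                 ba = c("b", "a"), bb = c("b", "b"))
  low <- list(aa = x, ab = x, ba = x, bb = x)
  high <- vector("list", levels)
  for (lev in seq_len(levels)) {
    bank <- if (lev == 1L) .stage1 else .qshift
    sub <- list()
    for (nm in names(combos)) {
      tr <- bank[[combos[[nm]][1]]]  # row tree (dimension 1)
      tc <- bank[[combos[[nm]][2]]]  # column tree (dimension 2)
      lo_r <- dt_analysis(low[[nm]], tr$lo, tr$lo_off, tr$phase)
      hi_r <- dt_analysis(low[[nm]], tr$hi, tr$hi_off, tr$phase)
      ll <- t(dt_analysis(t(lo_r), tc$lo, tc$lo_off, tc$phase))
      lh <- t(dt_analysis(t(lo_r), tc$hi, tc$hi_off, tc$phase))
      hl <- t(dt_analysis(t(hi_r), tc$lo, tc$lo_off, tc$phase))
      hh <- t(dt_analysis(t(hi_r), tc$hi, tc$hi_off, tc$phase))
      sub[[nm]] <- list(lh = lh, hl = hl, hh = hh)
      low[[nm]] <- ll
    }
    comb <- function(band) {
      aa <- sub$aa[[band]]; ab <- sub$ab[[band]]
      ba <- sub$ba[[band]]; bb <- sub$bb[[band]]
      list(p = ((aa - bb) + 1i * (ab + ba)) / sqrt(2),
           m = ((aa + bb) + 1i * (ab - ba)) / sqrt(2))
    }
    lh <- comb("lh"); hl <- comb("hl"); hh <- comb("hh")
    high[[lev]] <- list(lh$p, lh$m, hl$p, hl$m, hh$p, hh$m)
  }
  list(lowpass = low, highpass = high, levels = levels, dim_in = dim_in)
}

# Reconstruction from the lowpass branch only (all highpass subbands zero):
# invert each tree's lowpass chain and average the four tree reconstructions.
dtcwt_base <- function(fw) {
  combos <- list(aa = c("a", "a"), ab = c("a", "b"),
                 ba = c("b", "a"), bb = c("b", "b"))
  acc <- NULL
  for (nm in names(combos)) {
    y <- fw$lowpass[[nm]]
    for (lev in seq(fw$levels, 1L)) {
      bank <- if (lev == 1L) .stage1 else .qshift
      tr <- bank[[combos[[nm]][1]]]
      tc <- bank[[combos[[nm]][2]]]
      y <- t(dt_synthesis(t(y), tc$syn, tc$syn_off, tc$phase, 2L * ncol(y)))
      y <- dt_synthesis(y, tr$syn, tr$syn_off, tr$phase, 2L * nrow(y))
    }
    acc <- if (is.null(acc)) y else acc + y
  }
  (acc / 4)[seq_len(fw$dim_in[1]), seq_len(fw$dim_in[2]), drop = FALSE]
}
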