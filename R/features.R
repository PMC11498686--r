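#' Multi-level deep feature extraction for the detail-fusion branch
#'
#' The detail-fusion strategy consumes four rectified feature levels per
#' source: level `i` has `64 * 2^(i-1)` channels at `ceil(H / 2^(i-1)) x
#' ceil(W / 2^(i-1))` spatial size (channel counts 64, 128, 256, 512;
#' level 1 at the input resolution). Any object honouring this contract can
#' drive the fusion; two extractors are provided:
#'
#' * [make_fixture_extractor()] — a deterministic, download-free bank of
#'   seeded random 3x3 convolutions with ReLU and stride-2 average pooling
#'   between stages. No trained weights; its role is to provide a valid,
#'   reproducible activity signal for testing and default operation.
#' * [make_vgg19_extractor()] — an adapter exposing the relu1_1, relu2_1,
#'   relu3_1 and relu4_1 activations of a pretrained VGG-19, given a weights
#'   file supplied by the user (weights are never downloaded implicitly).
#'
#' @name deep_features
NULL

#' Extract a four-level feature stack from a detail image
#'
#' @param detail Numeric matrix (a detail part; may contain negative values).
#' @param extractor A feature-extractor handle from
#'   [make_fixture_extractor()] or [make_vgg19_extractor()].
#' @return An object of class `feature_stack`: list with `levels` (four
#'   arrays H_i x W_i x C_i) and `extractor_id`.
#' @export
extract_features <- function(detail, extractor) {
  detail <- px(detail)
  if (!is.matrix(detail))
    stop_medfuse("medfuse_validation", "detail must be a single-channel matrix")
  levels <- extractor$forward(extractor$prepare(detail))
  validate_feature_levels(levels, dim(detail))
  structure(list(levels = levels, extractor_id = extractor$id),
            class = "feature_stack")
}

validate_feature_levels <- function(levels, dim_in) {
  if (length(levels) != 4L)
    stop_medfuse("medfuse_contract",
                 sprintf("extractor returned %d levels, expected 4", length(levels)))
  for (i in 1:4) {
    d <- dim(levels[[i]])
    want_c <- 64L * 2L^(i - 1L)
    want_h <- ceiling(dim_in[1] / 2^(i - 1))
    want_w <- ceiling(dim_in[2] / 2^(i - 1))
    if (length(d) != 3L || d[3] != want_c)
      stop_medfuse("medfuse_contract",
                   sprintf("level %d: expected %d channels, got %s",
                           i, want_c, paste(d, collapse = "x")))
    if (d[1] != want_h || d[2] != want_w)
      stop_medfuse("medfuse_contract",
                   sprintf("level %d: expected %dx%d spatial size, got %dx%d",
                           i, want_h, want_w, d[1], d[2]))
  }
  invisible(TRUE)
}

#' Deterministic fixture feature extractor
#'
#' Four stages of bias-free 3x3 convolutions (kernels drawn once from a
#' seeded He-scaled normal initialiser), ReLU, and stride-2 average pooling
#' between stages, with channel counts 64, 128, 256, 512. Fully
#' deterministic given the seed; no downloads or trained weights.
#'
#' @param seed Integer seed for the kernel draw.
#' @return A feature-extractor handle.
#' @export
make_fixture_extractor <- function(seed = 1L) {
  channels <- c(64L, 128L, 256L, 512L)
  kernels <- with_seed(seed, {
    cin <- 1L
    lapply(channels, function(cout) {
      w <- matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                  9L * cin, cout)
      cin <<- cout
      w
    })
  })
  forward <- function(x) {
    a <- array(x, c(nrow(x), ncol(x), 1L, 1L))
    out <- vector("list", 4L)
    for (s in 1:4) {
      if (s > 1L) a <- avg_pool2(a)
      a <- relu(conv_forward(a, kernels[[s]], k = 3L, pad = 1L)$out)
      d <- dim(a)
      out[[s]] <- array(a, d[1:3])
    }
    out
  }
  list(id = sprintf("fixture[seed=%d]", as.integer(seed)),
       prepare = function(detail) detail,  # bias-free net: keep zero at zero
       forward = forward,
       kernels = kernels)
}

#' VGG-19 feature-extractor adapter
#'
#' Exposes the relu1_1, relu2_1, relu3_1 and relu4_1 activations of a
#' pretrained VGG-19. Weights must be supplied as an RDS file holding a
#' named list of conv layers (`conv1_1`, `conv1_2`, `conv2_1`, `conv2_2`,
#' `conv3_1` ... `conv3_4`, `conv4_1`), each a list with `w` (array
#' k x k x cin x cout) and `b` (length-cout bias). The detail image is
#' shifted into \[0, 1\], replicated to three channels, and normalised with
#' the natural-image mean/std convention (0.485/0.456/0.406,
#' 0.229/0.224/0.225). Max pooling uses ceiling semantics so odd input
#' sizes honour the level-size contract.
#'
#' @param weights_path Path to the RDS weights file.
#' @return A feature-extractor handle.
#' @export
make_vgg19_extractor <- function(weights_path) {
  if (is.null(weights_path) || !file.exists(weights_path))
    stop_medfuse("medfuse_param", paste0(
      "VGG-19 weights not found at '", weights_path, "'. Supply a weights RDS ",
      "file, or use the deterministic fixture extractor ",
      "(make_fixture_extractor(seed)) which needs no downloads."))
  wts <- readRDS(weights_path)
  need <- c("conv1_1", "conv1_2", "conv2_1", "conv2_2",
            "conv3_1", "conv3_2", "conv3_3", "conv3_4", "conv4_1")
  if (!all(need %in% names(wts)))
    stop_medfuse("medfuse_param",
                 paste("weights file is missing layers:",
                       paste(setdiff(need, names(wts)), collapse = ", ")))
  mean3 <- c(0.485, 0.456, 0.406); std3 <- c(0.229, 0.224, 0.225)
  prepare <- function(detail) {
    x <- clip01(detail + 0.5)
    a <- array(0, c(nrow(x), ncol(x), 3L, 1L))
    for (c3 in 1:3) a[, , c3, 1] <- (x - mean3[c3]) / std3[c3]
    a
  }
  conv <- function(a, layer) {
    w <- wts[[layer]]$w
    k <- dim(w)[1]
    wmat <- matrix(w, k * k * dim(w)[3], dim(w)[4])
    relu(conv_forward(a, wmat, k = k, pad = (k - 1L) %/% 2L, bias = wts[[layer]]$b)$out)
  }
  max_pool2 <- function(x) {
    d <- dim(x)
    if (d[1] %% 2L == 1L) { x <- x[c(seq_len(d[1]), d[1]), , , , drop = FALSE]; d <- dim(x) }
    if (d[2] %% 2L == 1L) { x <- x[, c(seq_len(d[2]), d[2]), , , drop = FALSE]; d <- dim(x) }
    o <- pmax(x[seq(1, d[1], 2), , , , drop = FALSE], x[seq(2, d[1], 2), , , , drop = FALSE])
    pmax(o[, seq(1, d[2], 2), , , drop = FALSE], o[, seq(2, d[2], 2), , , drop = FALSE])
  }
  forward <- function(a) {
    l1 <- conv(a, "conv1_1")
    a2 <- max_pool2(conv(l1, "conv1_2"))
    l2 <- conv(a2, "conv2_1")
    a3 <- max_pool2(conv(l2, "conv2_2"))
    l3 <- conv(a3, "conv3_1")
    a4 <- l3
    for (nm in c("conv3_2", "conv3_3", "conv3_4")) a4 <- conv(a4, nm)
    l4 <- conv(max_pool2(a4), "conv4_1")
    lapply(list(l1, l2, l3, l4), function(x) array(x, dim(x)[1:3]))
  }
  list(id = paste0("vgg19[", basename(weights_path), "]"),
       prepare = prepare, forward = forward)
}

#' Validate a feature extractor against the four-level contract
#'
#' Runs the extractor twice on a probe image and checks level count,
#' channel/stride schedule, determinism and non-negativity. Errors (class
#' `medfuse_contract`) name the offending level.
#'
#' @param extractor A feature-extractor handle.
#' @param probe Optional probe matrix; default is a fixed 33 x 47 ramp
#'   (odd sizes exercise the ceiling rule).
#' @return `TRUE`, invisibly.
#' @export
check_extractor <- function(extractor, probe = NULL) {
  if (is.null(probe))
    probe <- matrix(seq(-0.5, 0.5, length.out = 33 * 47), 33, 47)
  f1 <- extract_features(probe, extractor)
  f2 <- extract_features(probe, extractor)
  for (i in 1:4) {
    if (!identical(f1$levels[[i]], f2$levels[[i]]))
      stop_medfuse("medfuse_contract",
                   sprintf("level %d: extractor is not deterministic", i))
    if (min(f1$levels[[i]]) < 0)
      stop_medfuse("medfuse_contract",
                   sprintf("level %d: negative activations (outputs must be rectified)", i))
  }
  invisible(TRUE)
}

#' @export
print.feature_stack <- function(x, ...) {
  cat("<feature_stack>", x$extractor_id, "\n")
  for (i in 1:4) {
    d <- dim(x$levels[[i]])
    cat(sprintf("  level %d: %d x %d x %d\n", i, d[1], d[2], d[3]))
  }
  invisible(x)
}
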