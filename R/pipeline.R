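#' Fusion pipeline configuration
#'
#' Every knob of the two-branch fusion in one flat record. All fields have
#' defaults; a config round-trips losslessly through its on-disk YAML form
#' ([write_config()] / [read_config()]).
#'
#' @param decomposition `"optimization"` (gradient-penalised two-scale
#'   split) or `"dtcwt"`.
#' @param lam Gradient penalty lambda for the optimization backend.
#' @param levels Decomposition depth for the dtcwt backend.
#' @param base_mode `"scalar"` (fixed weights) or `"snn"` (Siamese
#'   per-pixel weight map).
#' @param alpha Length-2 scalar base weights summing to 1.
#' @param extractor `"fixture"` or `"vgg19"`.
#' @param extractor_seed Seed for the fixture extractor kernels.
#' @param vgg_weights Path to VGG-19 weights (RDS), required for
#'   `extractor = "vgg19"`.
#' @param snn_weights Path to a saved Siamese model, required for
#'   `base_mode = "snn"` unless a model object is passed to [fuse_images()].
#' @param stride Siamese dense-inference stride.
#' @param r Block-average radius for the detail activity maps.
#' @param register Register image 2 onto image 1 before fusing.
#' @param register_cost `"ssd"` or `"mi"`.
#' @param diffuse Apply Perona-Malik diffusion to both inputs.
#' @param equalize Apply histogram equalisation to both inputs.
#' @param output_bit_depth 8 or 16.
#' @param chroma_reinject Recompose colour output from a colour source's
#'   stored chroma.
#' @return Class `fusion_config`.
#' @export
fusion_config <- function(decomposition = c("optimization", "dtcwt"),
                          lam = 5, levels = 2L,
                          base_mode = c("scalar", "snn"),
                          alpha = c(0.5, 0.5),
                          extractor = c("fixture", "vgg19"),
                          extractor_seed = 1L,
                          vgg_weights = "",
                          snn_weights = "",
                          stride = 2L, r = 1L,
                          register = FALSE, register_cost = "ssd",
                          diffuse = FALSE, equalize = FALSE,
                          output_bit_depth = 8L,
                          chroma_reinject = FALSE) {
  cfg <- list(decomposition = match.arg(decomposition),
              lam = lam, levels = as.integer(levels),
              base_mode = match.arg(base_mode), alpha = alpha,
              extractor = match.arg(extractor),
              extractor_seed = as.integer(extractor_seed),
              vgg_weights = vgg_weights, snn_weights = snn_weights,
              stride = as.integer(stride), r = as.integer(r),
              register = isTRUE(register), register_cost = register_cost,
              diffuse = isTRUE(diffuse), equalize = isTRUE(equalize),
              output_bit_depth = as.integer(output_bit_depth),
              chroma_reinject = isTRUE(chroma_reinject))
  structure(cfg, class = "fusion_config")
}

#' @rdname fusion_config
#' @param cfg A `fusion_config`.
#' @param path File path for the flat YAML form.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "fusion_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname fusion_config
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop_medfuse("medfuse_param", sprintf("no config file at '%s'", path))
  vals <- yaml::read_yaml(path)
  do.call(fusion_config, vals)
}

#' @export
print.fusion_config <- function(x, ...) {
  cat("<fusion_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-16s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  invisible(x)
}

get_extractor <- function(cfg) {
  if (cfg$extractor == "fixture") make_fixture_extractor(cfg$extractor_seed)
  else make_vgg19_extractor(cfg$vgg_weights)
}

#' Fuse two co-registered images
#'
#' Runs the full two-branch pipeline: optional pre-processing
#' (registration of image 2 onto image 1, Perona-Malik diffusion,
#' histogram equalisation — all off by default), two-scale decomposition of
#' each source, base-part fusion (scalar weighted sum or Siamese weight
#' map), deep-feature detail fusion, and reconstruction
#' `F = F_b + F_d` clipped to \[0, 1\].
#'
#' @param img1,img2 `image_plane`s or matrices in \[0, 1\]. Must share one
#'   shape unless `register` is enabled in the config.
#' @param config A [fusion_config()].
#' @param snn Optional `snn_model`/`snn_fit` for `base_mode = "snn"`
#'   (otherwise loaded from `config$snn_weights`).
#' @return Class `fused_image`: `pixels` (an `image_plane`), the fused
#'   `base` and `detail` branches, the `config`, and a `provenance` record
#'   (input shapes, extractor id, component checksums).
#' @export
fuse_images <- function(img1, img2, config = fusion_config(), snn = NULL) {
  i1 <- as_image_plane(px(img1))
  i2 <- as_image_plane(px(img2))
  if (!all(dim(px(i1)) == dim(px(i2)))) {
    if (!config$register)
      stop_medfuse("medfuse_validation",
                   "images differ in shape; enable registration (register_rigid) or resample first")
    stop_medfuse("medfuse_validation",
                 "rigid registration cannot reconcile different image sizes; crop or resample first")
  }
  if (config$register) {
    reg <- register_rigid(i2, i1, cost = config$register_cost)
    i2 <- reg$image
  }
  if (config$diffuse) { i1 <- anisodiffuse(i1); i2 <- anisodiffuse(i2) }
  if (config$equalize) { i1 <- hist_equalize(i1); i2 <- hist_equalize(i2) }

  d1 <- decompose(px(i1), config$decomposition, lam = config$lam, levels = config$levels)
  d2 <- decompose(px(i2), config$decomposition, lam = config$lam, levels = config$levels)

  if (config$base_mode == "snn") {
    model <- if (!is.null(snn)) snn else snn_load(config$snn_weights)
    W <- snn_weight_map(d1$base, d2$base, model, stride = config$stride)
    fb <- fuse_base(d1$base, d2$base, mode = "snn", weight_map = W)
  } else {
    fb <- fuse_base(d1$base, d2$base, mode = "scalar", alpha = config$alpha)
  }

  ex <- get_extractor(config)
  s1 <- extract_features(d1$detail, ex)
  s2 <- extract_features(d2$detail, ex)
  df <- detail_fuse(list(d1$detail, d2$detail), list(s1, s2), r = config$r)
  fd <- df$combined

  fused <- clip01(fb + fd)
  structure(list(
    pixels = image_plane(fused, bit_depth = config$output_bit_depth,
                         meta = list(fused = TRUE)),
    base = fb, detail = fd, config = config,
    provenance = list(
      input_dims = dim(px(i1)),
      extractor_id = ex$id,
      checksums = list(img1 = component_checksum(px(i1)),
                       img2 = component_checksum(px(i2)),
                       base = component_checksum(fb),
                       detail = component_checksum(fd),
                       fused = component_checksum(fused)))),
    class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  cat(sprintf("<fused_image> %d x %d (%s decomposition, %s base, %s)\n",
              nrow(px(x$pixels)), ncol(px(x$pixels)),
              x$config$decomposition, x$config$base_mode,
              x$provenance$extractor_id))
  cat(sprintf("  base range [%.4f, %.4f], detail range [%.4f, %.4f]\n",
              min(x$base), max(x$base), min(x$detail), max(x$detail)))
  invisible(x)
}

#' @export
summary.fused_image <- function(object, ...) {
  print(object)
  cat("  provenance checksums:\n")
  for (nm in names(object$provenance$checksums))
    cat(sprintf("    %-7s %s\n", nm, object$provenance$checksums[[nm]]))
  invisible(object)
}

#' @export
plot.fused_image <- function(x, ...) plot(x$pixels, ...)

#' Re-inject chroma into a fused luminance image
#'
#' Recomposes a colour image by replacing the luminance channel of a colour
#' source (typically the pseudo-coloured functional image) with the fused
#' luminance, using the Cb/Cr planes stored by [read_image()].
#'
#' @param fused A `fused_image` or luminance matrix.
#' @param color_source An `image_plane` read from a colour file (its
#'   `meta$chroma` must be present).
#' @return H x W x 3 RGB array in \[0, 1\].
#' @export
chroma_reinject <- function(fused, color_source) {
  y <- if (inherits(fused, "fused_image")) px(fused$pixels) else px(fused)
  if (!inherits(color_source, "image_plane") || is.null(color_source$meta$chroma))
    stop_medfuse("medfuse_param",
                 "color_source carries no stored chroma (was it read from a colour file?)")
  cb <- color_source$meta$chroma$cb
  cr <- color_source$meta$chroma$cr
  if (!all(dim(cb) == dim(y)))
    stop_medfuse("medfuse_validation", "fused image and chroma planes differ in shape")
  r <- y + (1 - 0.299) / 0.5 * cr
  b <- y + (1 - 0.114) / 0.5 * cb
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(nrow(y), ncol(y), 3L))
  out[, , 1] <- clip01(r); out[, , 2] <- clip01(g); out[, , 3] <- clip01(b)
  out
}
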