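Package: medfuse
Title: Two-Branch Multimodal Medical Image Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fuses pairs of co-registered single-channel medical images
    (e.g. MRI/PET, CT/MRI) by a two-branch strategy: each source is split
    into a smooth base part and a residual detail part by a gradient
    penalised two-scale decomposition (or a dual-tree complex wavelet
    alternative); base parts are combined by a weighted sum whose weights
    may come from a Siamese patch-saliency network, detail parts by
    multi-layer deep-feature activity maps with softmax weighting and
    cross-level maximum selection. Includes rigid intensity-based
    registration, Perona-Malik diffusion and histogram equalisation
    pre-processing, a fusion quality metric suite (MSE, PSNR, SSIM,
    normalised mutual information, multi-scale edge preservation), a
    deterministic synthetic multimodal pair generator, and a command line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
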