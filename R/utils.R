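# Internal helpers shared across modules.

stop_medfuse <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "medfuse_error")))
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur with replicated borders. Radius covers 3 sigma.
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur_dim <- function(m) {
    h <- nrow(m)
    idx <- function(i) pmin(pmax(i, 1L), h)
    out <- matrix(0, h, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * m[idx(seq_len(h) + (j - r - 1L)), , drop = FALSE]
    }
    out
  }
  t(blur_dim(t(blur_dim(x))))
}

# Cheap content checksum used for provenance records (no digest dependency).
component_checksum <- function(x) {
  v <- as.numeric(x)
  sprintf("%dx%d:%.10g:%.10g", NROW(x), NCOL(x), sum(v), sum(v * seq_along(v) %% 97))
}
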