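# Shared test fixtures, all generated in code under fixed seeds.

rand_img <- function(h, w = h, seed = 1) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Smooth-ish test image with edges and texture (more realistic than white
# noise for pipeline-level checks).
phantom_img <- function(n = 64, seed = 1) {
  set.seed(seed)
  g <- outer(seq_len(n), seq_len(n), function(r, c)
    0.4 + 0.3 * sin(2 * pi * r / n) * cos(2 * pi * c / n))
  g[round(n / 4):round(n / 2), round(n / 3):round(2 * n / 3)] <- 0.85
  pmin(pmax(g + matrix(rnorm(n * n, sd = 0.02), n, n), 0), 1)
}

# Dense oracle for the gradient-penalised decomposition: solve
# (I + lam (Gx'Gx + Gy'Gy)) vec(b) = vec(x) with periodic first-difference
# matrices, independently of the FFT path.
dense_base_oracle <- function(x, lam) {
  h <- nrow(x); w <- ncol(x)
  circ_diff <- function(n) {
    D <- diag(-1, n)
    D[cbind(seq_len(n), c(2:n, 1))] <- 1
    D
  }
  Gx <- kronecker(circ_diff(w), diag(h))   # gradient across columns
  Gy <- kronecker(diag(w), circ_diff(h))   # gradient across rows
  A <- diag(h * w) + lam * (crossprod(Gx) + crossprod(Gy))
  matrix(solve(A, as.vector(x)), h, w)
}
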