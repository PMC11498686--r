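test_that("frequency-domain base solver matches the dense periodic oracle", {
  for (seed in 1:5) {
    x <- rand_img(8, seed = seed)
    d <- decompose_optimization(x, lam = 5)
    expect_lt(max(abs(d$base - dense_base_oracle(x, 5))), 1e-8)
  }
  # a different lambda, non-square image
  x <- rand_img(8, 12, seed = 11)
  d <- decompose_optimization(x, lam = 0.7)
  expect_lt(max(abs(d$base - dense_base_oracle(x, 0.7))), 1e-8)
})

test_that("base + detail reconstructs the input for both backends", {
  for (seed in 1:5) {
    x <- rand_img(33, 47, seed = seed)
    do <- decompose_optimization(x, 5)
    dd <- decompose_dtcwt(x, 2)
    expect_lt(max(abs(do$base + do$detail - x)), 1e-10)
    expect_lt(max(abs(dd$base + dd$detail - x)), 1e-10)
  }
})

test_that("lambda limits: base tends to the image or to its mean", {
  x <- rand_img(64, seed = 21)
  d0 <- decompose_optimization(x, 1e-12)
  expect_lt(max(abs(d0$detail)), 1e-6)
  dinf <- decompose_optimization(x, 1e6)
  expect_lt(max(abs(dinf$base - mean(x))), 1e-3)
})

test_that("optimization decomposition is linear in its input", {
  x <- rand_img(16, seed = 31); y <- rand_img(16, seed = 32)
  a <- 0.3; b <- 0.6
  lhs <- decompose_optimization(a * x + b * y, 5)$base
  rhs <- a * decompose_optimization(x, 5)$base + b * decompose_optimization(y, 5)$base
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("detail energy is non-decreasing in lambda", {
  x <- phantom_img(48, seed = 41)
  e <- vapply(c(0.1, 1, 5, 25),
              function(l) sqrt(sum(decompose_optimization(x, l)$detail^2)),
              numeric(1))
  expect_true(all(diff(e) >= 0))
})

test_that("base of the optimization backend stays within the image range", {
  for (seed in 1:5) {
    x <- rand_img(24, seed = seed)
    d <- decompose_optimization(x, 5)
    expect_gte(min(d$base), min(x) - 1e-12)
    expect_lte(max(d$base), max(x) + 1e-12)
  }
})

test_that("dtcwt backend: constants pass through, low frequencies stay in the base", {
  const <- matrix(0.37, 32, 32)
  d <- decompose_dtcwt(const, 2)
  expect_lt(max(abs(d$base - 0.37)), 1e-10)
  expect_lt(max(abs(d$detail)), 1e-10)

  n <- 64
  g <- outer(1:n, 1:n, function(r, c)
    0.5 + 0.4 * sin(2 * pi * r / n) * cos(2 * pi * c / n))
  d2 <- decompose_dtcwt(g, 2)
  expect_lt(sqrt(sum(d2$detail^2) / sum(g^2)), 0.05)
})

test_that("parameter validation rejects bad lambda and undersized images", {
  x <- rand_img(16, seed = 1)
  expect_error(decompose_optimization(x, 0), class = "medfuse_param")
  expect_error(decompose_optimization(x, -1), class = "medfuse_param")
  expect_error(decompose_dtcwt(rand_img(8, seed = 1), levels = 4),
               class = "medfuse_param")
})
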