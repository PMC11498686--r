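test_that("the identity transform leaves an image bit-identical", {
  x <- phantom_img(40, seed = 2)
  expect_identical(medfuse:::apply_rigid(x, 0, 0, 0), x)
})

test_that("SSD of two images differing in one pixel by 0.5 is 0.25", {
  a <- matrix(0.2, 10, 10)
  b <- a; b[3, 4] <- 0.7
  expect_equal(medfuse:::ssd_cost(a, b), 0.25)
})

test_that("registering an image to itself yields the zero transform", {
  x <- phantom_img(48, seed = 3)
  out <- register_rigid(x, x, cost = "ssd", refine = FALSE)
  expect_equal(out$transform$dx, 0)
  expect_equal(out$transform$dy, 0)
  expect_equal(out$transform$cost_value, 0)
})

test_that("SSD grid search recovers a known integer shift", {
  x <- phantom_img(64, seed = 4)
  moved <- medfuse:::apply_rigid(x, 3, -2, 0)
  out <- register_rigid(moved, x, cost = "ssd")
  expect_lt(abs(out$transform$dx - (-3)), 0.5)
  expect_lt(abs(out$transform$dy - 2), 0.5)
})

test_that("MI registration works and rejects a constant fixed image", {
  x <- phantom_img(48, seed = 5)
  moved <- medfuse:::apply_rigid(x, -2, 1, 0)
  out <- register_rigid(moved, x, cost = "mi",
                        search = list(dx = c(-3, 3), dy = c(-3, 3)))
  expect_lt(abs(out$transform$dx - 2), 0.5)
  expect_lt(abs(out$transform$dy - (-1)), 0.5)
  expect_error(register_rigid(x, matrix(0.5, 48, 48), cost = "mi"),
               class = "medfuse_degenerate")
})

test_that("diffusion preserves constants and edge locations", {
  const <- matrix(0.42, 32, 32)
  expect_equal(anisodiffuse(const, 10, 0.1), const)
  expect_identical(anisodiffuse(const, 0L, 0.1), const)

  # step edge of height 0.8 with kappa << step: edge position unchanged
  step <- cbind(matrix(0.1, 32, 16), matrix(0.9, 32, 16))
  out <- anisodiffuse(step, 10, 0.05)
  grad_in <- abs(diff(t(step)))[, 1]
  grad_out <- abs(diff(t(out)))[, 1]
  expect_equal(which.max(grad_out), which.max(grad_in))

  # large kappa approaches linear diffusion: an impulse decays monotonically
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  amp <- numeric(8); cur <- imp
  for (i in 1:8) { cur <- anisodiffuse(cur, 1, kappa = 10); amp[i] <- cur[11, 11] }
  expect_true(all(diff(amp) < 0))
})

test_that("preprocessing outputs stay in [0,1]", {
  x <- phantom_img(32, seed = 6)
  for (out in list(anisodiffuse(x, 5, 0.1), hist_equalize(x),
                   register_rigid(x, x)$image$pixels)) {
    m <- if (is.matrix(out)) out else out
    expect_gte(min(m), 0); expect_lte(max(m), 1)
  }
})

test_that("histogram equalisation maps levels to their CDF values", {
  # two-level image: 75% at 0.2, 25% at 0.8 -> CDF mapping {0.75, 1.0}
  x <- matrix(0.2, 20, 20)
  x[1:5, ] <- 0.8
  out <- hist_equalize(x)
  expect_equal(unique(out[x == 0.2]), 0.75)
  expect_equal(unique(out[x == 0.8]), 1.0)

  expect_identical(hist_equalize(matrix(0.3, 16, 16)), matrix(0.3, 16, 16))

  # an already-uniform 256-level image is (nearly) unchanged
  u <- matrix(rep(0:255 / 255, length.out = 256 * 4), 32, 32)
  out_u <- hist_equalize(u)
  expect_lt(max(abs(out_u - u)), 1 / 255 + 1e-12)
})
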