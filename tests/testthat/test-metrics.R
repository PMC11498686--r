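test_that("mse matches a brute-force oracle and the stated examples", {
  x <- rand_img(16, seed = 1)
  expect_equal(mse(x, x), 0)
  expect_equal(mse(matrix(0.5, 8, 8), matrix(0.5 + 16 / 255, 8, 8)), 256)
  a <- rand_img(4, seed = 2); b <- rand_img(4, seed = 3)
  want <- 0
  for (i in 1:4) for (j in 1:4) want <- want + (255 * (a[i, j] - b[i, j]))^2
  expect_equal(mse(a, b), want / 16)
  expect_error(mse(a, rand_img(5, seed = 1)), class = "medfuse_validation")
})

test_that("psnr follows 10*log10(MAX^2/MSE) with the infinity sentinel", {
  x <- rand_img(12, seed = 4)
  expect_identical(psnr(x, x), Inf)
  expect_equal(psnr(matrix(0, 8, 8), matrix(1, 8, 8)), 0)  # MSE = 255^2
  # MAX^2 / MSE = 1000 -> 30 dB
  delta <- sqrt(255^2 / 1000) / 255
  expect_equal(psnr(matrix(0.2, 8, 8), matrix(0.2 + delta, 8, 8)), 30)
})

test_that("psnr decreases strictly as mse increases", {
  base <- rand_img(16, seed = 5)
  deltas <- c(0.01, 0.03, 0.08, 0.2)
  ms <- vapply(deltas, function(d) mse(base, pmin(base + d, 1)), numeric(1))
  ps <- vapply(deltas, function(d) psnr(base, pmin(base + d, 1)), numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_true(all(diff(ps) < 0))
})

test_that("ssim is 1 for identical images, symmetric, negative for inverted structure", {
  x <- phantom_img(32, seed = 6)
  expect_identical(ssim(x, x), 1)
  y <- phantom_img(32, seed = 7)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  checker <- (outer(1:32, 1:32, `+`) %% 2) * 1
  expect_lt(ssim(checker, 1 - checker), 0)
  expect_error(ssim(matrix(0.5, 8, 8), matrix(0.5, 8, 8)), class = "medfuse_param")
})

test_that("q_mi: self-fusion of one image gives 2; independence gives near 0", {
  a <- rand_img(64, seed = 8)
  expect_equal(q_mi(a, a, a), 2, tolerance = 1e-12)
  expect_equal(q_mi(a, rand_img(64, seed = 9), a),
               q_mi(rand_img(64, seed = 9), a, a))  # a/b symmetry
  # independent noise shares (asymptotically) no information; the histogram
  # estimator's positive bias shrinks with sample size, hence the large image
  f <- rand_img(600, seed = 10)
  a2 <- rand_img(600, seed = 11); b2 <- rand_img(600, seed = 12)
  expect_lt(q_mi(a2, b2, f), 0.05)
  expect_error(q_mi(a, a, matrix(0.5, 64, 64)), class = "medfuse_degenerate")
  # unnormalised variant reduces to MI sums: for f == a == b it is 2 H(a)
  h <- medfuse:::entropy_bits(tabulate(medfuse:::hist256(a) + 1L, 256L))
  expect_equal(q_mi(a, a, a, normalized = FALSE), 2 * h, tolerance = 1e-9)
})

test_that("q_m scores perfect preservation 1, destroyed edges near 0, and decays under blur", {
  pair <- make_pair(3, c(64, 64))
  a <- pair$structural$pixels; b <- pair$functional$pixels
  expect_equal(q_m(a, a, a), 1)
  expect_lt(q_m(a, b, matrix(mean(a), 64, 64)), 0.1)
  sigmas <- c(0, 1, 2, 3, 4)
  scores <- vapply(sigmas, function(s)
    q_m(a, b, if (s == 0) a else medfuse:::gauss_blur(a, s)), numeric(1))
  expect_true(all(diff(scores) < 0))
})

test_that("fusion_metrics assembles the five metrics with a conventions block", {
  pair <- make_pair(4, c(64, 64))
  rep <- fusion_metrics(pair$structural, pair$functional, pair$composite)
  expect_s3_class(rep, "metric_report")
  rec <- as_record(rep)
  expect_true(all(c("mse_mean", "psnr_mean", "ssim_mean", "q_mi", "q_m",
                    "conventions") %in% names(rec)))
  expect_equal(rep$mse$mean, (rep$mse$a + rep$mse$b) / 2)
})
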