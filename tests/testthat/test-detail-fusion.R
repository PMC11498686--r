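test_that("activity map is the per-pixel L1 norm across channels", {
  expect_equal(activity_map(array(0, c(4, 4, 3))), matrix(0, 4, 4))

  toy <- array(0, c(1, 1, 2)); toy[1, 1, ] <- c(0.3, -0.4)
  expect_equal(activity_map(toy)[1, 1], 0.7)

  set.seed(12)
  lv <- array(rnorm(5 * 5 * 4), c(5, 5, 4))
  want <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) want[i, j] <- sum(abs(lv[i, j, ]))
  expect_equal(activity_map(lv), want)
})

test_that("block averaging matches a zero-padded box-filter oracle", {
  set.seed(13)
  C <- matrix(abs(rnorm(49)), 7, 7)
  expect_identical(block_average(C, 0L), C)

  got <- block_average(C, 1L)
  want <- matrix(0, 7, 7)
  for (x in 1:7) for (y in 1:7) {
    s <- 0
    for (b in -1:1) for (t in -1:1) {
      if (x + b >= 1 && x + b <= 7 && y + t >= 1 && y + t <= 7)
        s <- s + C[x + b, y + t]
    }
    want[x, y] <- s / 9
  }
  expect_equal(got, want)

  # constant map: interior keeps c, a corner keeps 4c/9 under zero padding
  cm <- matrix(0.9, 6, 6)
  ba <- block_average(cm, 1L)
  expect_equal(ba[3, 3], 0.9)
  expect_equal(ba[1, 1], 4 * 0.9 / 9)
})

test_that("softmax weights normalise activities with the uniform tie rule", {
  w <- softmax_weights(list(matrix(3, 2, 2), matrix(1, 2, 2)))
  expect_equal(w[[1]], matrix(0.75, 2, 2))
  expect_equal(w[[2]], matrix(0.25, 2, 2))

  eq <- softmax_weights(list(matrix(2, 3, 3), matrix(2, 3, 3)))
  expect_equal(eq[[1]], matrix(0.5, 3, 3))

  z <- softmax_weights(list(matrix(0, 2, 2), matrix(0, 2, 2)))
  expect_equal(z[[1]], matrix(0.5, 2, 2))

  expect_error(softmax_weights(list(matrix(-1, 2, 2), matrix(1, 2, 2))),
               class = "medfuse_validation")
})

test_that("upsampling replicates blocks and crops to odd targets exactly", {
  w1 <- matrix(runif(9), 3, 3)
  expect_identical(upsample_weights(w1, c(3, 3), 1L), w1)

  w3 <- matrix(1:4 / 10, 2, 2)
  up <- upsample_weights(w3, c(8, 8), 3L)
  expect_equal(dim(up), c(8L, 8L))
  for (i in 1:8) for (j in 1:8)
    expect_equal(up[i, j], w3[ceiling(i / 4), ceiling(j / 4)])

  set.seed(14)
  w2 <- matrix(runif(16), 4, 4)
  up2 <- upsample_weights(w2, c(7, 7), 2L)
  want <- matrix(0, 7, 7)
  for (i in 1:7) for (j in 1:7) want[i, j] <- w2[ceiling(i / 2), ceiling(j / 2)]
  expect_identical(up2, want)

  expect_error(upsample_weights(w2, c(20, 20), 2L), class = "medfuse_param")
})

test_that("per-level fusion and the cross-level maximum match a brute-force oracle", {
  set.seed(15)
  d1 <- matrix(rnorm(36), 6, 6); d2 <- matrix(rnorm(36), 6, 6)
  wmaps <- lapply(1:4, function(i) {
    w <- matrix(runif(36), 6, 6)
    list(w, 1 - w)
  })
  res <- fuse_detail_contents(list(d1, d2), wmaps)
  for (i in 1:4) {
    want <- wmaps[[i]][[1]] * d1 + wmaps[[i]][[2]] * d2
    expect_lt(max(abs(res$per_level[[i]] - want)), 1e-12)
  }
  want_max <- matrix(0, 6, 6)
  for (x in 1:6) for (y in 1:6)
    want_max[x, y] <- max(vapply(res$per_level, function(m) m[x, y], numeric(1)))
  expect_identical(res$combined, want_max)
})

test_that("degenerate weights reduce fusion to a single source", {
  set.seed(16)
  d1 <- matrix(rnorm(25), 5, 5); d2 <- matrix(rnorm(25), 5, 5)
  ones <- lapply(1:4, function(i) list(matrix(1, 5, 5), matrix(0, 5, 5)))
  expect_equal(fuse_detail_contents(list(d1, d2), ones)$combined, d1)

  same <- lapply(1:4, function(i) { w <- matrix(runif(25), 5, 5); list(w, 1 - w) })
  expect_lt(max(abs(fuse_detail_contents(list(d1, d1), same)$combined - d1)), 1e-12)
})

test_that("whole detail branch: normalisation, convexity and swap equivariance", {
  x1 <- rand_img(33, 47, seed = 17) - 0.5
  x2 <- rand_img(33, 47, seed = 18) - 0.5
  ex <- make_fixture_extractor(2)
  s1 <- extract_features(x1, ex); s2 <- extract_features(x2, ex)

  # reproduce the internal weight maps and check exact normalisation
  for (i in 1:4) {
    finals <- list(block_average(activity_map(s1$levels[[i]]), 1L),
                   block_average(activity_map(s2$levels[[i]]), 1L))
    w <- lapply(softmax_weights(finals), upsample_weights,
                target = c(33, 47), level = i)
    expect_identical(w[[1]] + w[[2]], matrix(1, 33, 47))
  }

  res <- detail_fuse(list(x1, x2), list(s1, s2))
  lo <- pmin(x1, x2); hi <- pmax(x1, x2)
  for (m in c(res$per_level, list(res$combined))) {
    expect_true(all(m >= lo - 1e-12))
    expect_true(all(m <= hi + 1e-12))
  }

  swapped <- detail_fuse(list(x2, x1), list(s2, s1))
  expect_identical(res$combined, swapped$combined)

  rerun <- detail_fuse(list(x1, x2),
                       list(extract_features(x1, make_fixture_extractor(2)),
                            extract_features(x2, make_fixture_extractor(2))))
  expect_identical(res$combined, rerun$combined)
})
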