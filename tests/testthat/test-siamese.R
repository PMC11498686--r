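test_that("branch geometry matches the layer schedule", {
  m <- build_snn(1)
  expect_equal(m$spec$patch_size, 16L)
  expect_equal(m$spec$branch_output_dim, 256L)
  x <- array(rand_img(16, seed = 1), c(16, 16, 1, 1))
  br <- medfuse:::snn_branch_forward(m$params, x)
  expect_equal(nrow(br$out), 256L)                 # 256-dim branch vector
  expect_equal(dim(br$a1)[1:2], c(16L, 16L))       # conv1 preserves 16x16
  expect_equal(dim(br$a2)[1:2], c(16L, 16L))       # conv2 preserves 16x16
  expect_equal(dim(br$pl$out)[1:2], c(8L, 8L))     # pool to 8x8
  expect_equal(dim(br$a3)[1:2], c(8L, 8L))         # conv3 keeps 8x8
})

test_that("softmax head outputs a 2-probability vector and scores are swap-equivariant", {
  m <- build_snn(2)
  set.seed(3)
  a <- array(runif(16 * 16 * 4), c(16, 16, 4))
  b <- array(runif(16 * 16 * 4), c(16, 16, 4))
  p <- medfuse:::snn_forward_pair(m, a, b)
  expect_equal(dim(p), c(2L, 4L))
  expect_equal(colSums(p), rep(1, 4), tolerance = 1e-6)
  s_ab <- snn_score(m, a, b)
  s_ba <- snn_score(m, b, a)
  expect_equal(s_ab + s_ba, rep(1, 4), tolerance = 1e-6)
  expect_true(all(s_ab >= 0 & s_ab <= 1))
})

test_that("patch pairs are deterministic, balanced, in range, and refuse a label-free task", {
  p1 <- make_patch_pairs(5, 200)
  p2 <- make_patch_pairs(5, 200)
  expect_identical(p1, p2)
  expect_lt(abs(mean(p1$labels) - 0.5), 0.05)
  expect_gte(min(p1$a, p1$b), 0)
  expect_lte(max(p1$a, p1$b), 1)
  expect_gt(max(abs(make_patch_pairs(6, 50)$a - p1$a[, , 1:50])), 0)
  expect_error(make_patch_pairs(1, 100, blur_sigma = NULL, contrast_range = NULL),
               class = "medfuse_param")
})

test_that("an untrained model scores near chance; a briefly trained one learns", {
  pp <- make_patch_pairs(11, 240)
  m <- build_snn(11)
  s <- snn_score(m, pp$a, pp$b)
  acc0 <- mean((s > 0.5) == (pp$labels == 1L))
  # random initial weights give roughly chance-level accuracy, though the
  # deterministic head can carry a systematic bias on a correlated task
  expect_gt(acc0, 0.2); expect_lt(acc0, 0.8)
  fit <- train_snn(m, pp, epochs = 6, learning_rate = 0.02, seed = 2)
  expect_gt(fit$accuracy, acc0)
  # loss is non-increasing over most epochs
  expect_gte(mean(diff(fit$loss_history) <= 1e-6), 0.8)
})

test_that("weight maps cover the image, stay in [0,1], and average to 1/2 with swapped inputs", {
  m <- build_snn(4)
  x1 <- phantom_img(40, seed = 1); x2 <- phantom_img(40, seed = 2)
  W <- snn_weight_map(x1, x2, m, stride = 4)
  expect_equal(dim(W), c(40L, 40L))
  expect_gte(min(W), 0); expect_lte(max(W), 1)
  W2 <- snn_weight_map(x2, x1, m, stride = 4)
  expect_equal(W + W2, matrix(1, 40, 40), tolerance = 1e-6)
  expect_error(snn_weight_map(x1, x2, m, stride = 20), class = "medfuse_param")
  expect_error(snn_weight_map(x1[1:10, 1:10], x2[1:10, 1:10], m),
               class = "medfuse_validation")
})

test_that("save/load round-trips the model with its spec", {
  m <- build_snn(9)
  tmp <- withr::local_tempfile(fileext = ".rds")
  snn_save(m, tmp)
  back <- snn_load(tmp)
  expect_s3_class(back, "snn_model")
  expect_identical(back$params, m$params)
  expect_identical(back$spec$seed, 9L)
  expect_error(snn_load("missing.rds"), class = "medfuse_param")
})
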