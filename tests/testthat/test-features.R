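test_that("fixture extractor satisfies the four-level contract, odd sizes included", {
  ex <- make_fixture_extractor(1)
  expect_true(check_extractor(ex))           # runs on a 33x47 probe
  fs <- extract_features(rand_img(64, seed = 2) - 0.5, ex)
  dims <- t(vapply(fs$levels, dim, integer(3)))
  expect_equal(dims[, 3], c(64L, 128L, 256L, 512L))
  expect_equal(dims[, 1], c(64L, 32L, 16L, 8L))
  expect_equal(dims[, 2], c(64L, 32L, 16L, 8L))
})

test_that("zero input yields all-zero features (bias-free bank)", {
  ex <- make_fixture_extractor(3)
  fs <- extract_features(matrix(0, 32, 32), ex)
  for (lv in fs$levels) expect_equal(max(abs(lv)), 0)
})

test_that("fixture extractor is seed-deterministic and seed-sensitive", {
  x <- rand_img(32, seed = 5) - 0.5
  f1 <- extract_features(x, make_fixture_extractor(7))
  f2 <- extract_features(x, make_fixture_extractor(7))
  expect_identical(f1$levels, f2$levels)
  k1 <- make_fixture_extractor(1)$kernels[[1]]
  k2 <- make_fixture_extractor(2)$kernels[[1]]
  expect_gt(max(abs(k1 - k2)), 0)
})

test_that("contract violations are caught and name the level", {
  bad <- list(id = "bad", prepare = identity,
              forward = function(x) {
                ex <- make_fixture_extractor(1)
                lv <- ex$forward(x)
                lv[[2]] <- lv[[2]][, , 1:64]  # wrong channel count
                lv
              })
  expect_error(extract_features(rand_img(32, seed = 1), bad),
               "level 2", class = "medfuse_contract")
})

test_that("the VGG adapter demands a weights file and errors actionably", {
  expect_error(make_vgg19_extractor("nowhere/vgg19.rds"),
               "fixture", class = "medfuse_param")
})

test_that("a synthetic VGG-format weights file drives the adapter correctly", {
  # small random weights in the documented layout: enough to validate the
  # adapter's plumbing (channel schedule, pooling, rectification)
  set.seed(99)
  mk <- function(cin, cout) list(w = array(rnorm(9 * cin * cout, sd = 0.05),
                                           c(3, 3, cin, cout)),
                                 b = rnorm(cout, sd = 0.01))
  wts <- list(conv1_1 = mk(3, 64), conv1_2 = mk(64, 64),
              conv2_1 = mk(64, 128), conv2_2 = mk(128, 128),
              conv3_1 = mk(128, 256), conv3_2 = mk(256, 256),
              conv3_3 = mk(256, 256), conv3_4 = mk(256, 256),
              conv4_1 = mk(256, 512))
  tmp <- withr::local_tempfile(fileext = ".rds")
  saveRDS(wts, tmp)
  ex <- make_vgg19_extractor(tmp)
  fs <- extract_features(rand_img(33, 40, seed = 1) - 0.5, ex)
  dims <- t(vapply(fs$levels, dim, integer(3)))
  expect_equal(dims[, 3], c(64L, 128L, 256L, 512L))
  expect_equal(dims[, 1], c(33L, 17L, 9L, 5L))
  expect_gte(min(vapply(fs$levels, min, numeric(1))), 0)
})
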