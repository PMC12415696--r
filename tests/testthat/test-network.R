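# a frozen toy extractor: fixed seeded random projection of channel means
toy_extractor <- function(dim_out, input_size = 224, seed = 99) {
  proj <- hawkshead:::with_seed(seed, matrix(rnorm(12 * dim_out), 12, dim_out))
  function(x) {
    n <- dim(x)[4]
    feats <- t(vapply(seq_len(n), function(i) {
      img <- x[, , , i]
      q <- c(apply(img, 3, mean), apply(img, 3, sd),
             apply(img, 3, max), apply(img, 3, min))
      as.numeric(q %*% proj)
    }, numeric(dim_out)))
    matrix(feats, n, dim_out)
  }
}

test_that("HawksheadNet has the prescribed layer sequence and widths", {
  m <- build_hawkshead(hawkshead_spec(), seed = 1)
  layers <- model_layers(m)
  expect_equal(layers$type,
               c("input", "conv2d", "maxpool2d", "conv2d", "maxpool2d",
                 "gap", "dropout", "dense", "dense", "dense_sigmoid"))
  expect_equal(layers$output,
               c(3L, 128L, 128L, 64L, 64L, 64L, 64L, 128L, 64L, 1L))
  # the GAP output width is forced to the second conv's filter count
  expect_equal(layers$output[layers$layer == "global_average_pool"], 64L)
  expect_equal(dim(m$weights$U1), c(64L, 128L))
})

test_that("parameter counts match the closed-form layer arithmetic", {
  m <- build_hawkshead(hawkshead_spec(), seed = 1)
  expect_equal(count_params(m), 3584L + 73792L + 8320L + 8256L + 65L)
  expect_equal(count_params(m), 94017L)
  # transfer-learning head: 32 D + 32 + 16*32 + 16 + 16 + 1 = 32 D + 577
  tl8 <- build_tl_head(toy_extractor(8), feature_dim = 8)
  expect_equal(count_params(tl8), 32L * 8L + 577L)
  expect_equal(count_params(tl8), 833L)
  tl12 <- build_tl_head(toy_extractor(12), feature_dim = 12)
  expect_equal(count_params(tl12), 32L * 12L + 577L)
})

test_that("forward passes stay in [0, 1]; a zeroed output layer scores 0.5", {
  sp <- hawkshead_spec(input_size = 32L)
  m <- build_hawkshead(sp, seed = 2)
  x <- array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8))
  s <- predict(m, x)
  expect_length(s, 8L)
  expect_true(all(s >= 0 & s <= 1))
  m$weights$U3[] <- 0
  m$weights$c3[] <- 0
  expect_equal(predict(m, x), rep(0.5, 8))
})

test_that("predictions are independent of batch partitioning", {
  sp <- hawkshead_spec(input_size = 32L)
  m <- build_hawkshead(sp, seed = 3)
  x <- array(runif(32 * 32 * 3 * 7), c(32, 32, 3, 7))
  all_at_once <- predict(m, x)
  one_by_one <- vapply(1:7, function(i) predict(m, x[, , , i, drop = FALSE]),
                       numeric(1))
  expect_lt(max(abs(all_at_once - one_by_one)), 1e-6)
})

test_that("preprocessing resizes bilinearly, scales to [0,1], checks shapes", {
  tile <- array(180, dim = c(512, 512, 3))
  out <- preprocess_tiles(tile, 128)
  expect_equal(dim(out), c(128L, 128L, 3L, 1L))
  expect_true(all(abs(out - 180 / 255) < 1e-12))
  expect_true(all(out >= 0 & out <= 1))
  expect_error(preprocess_tiles(array(1, dim = c(256, 256, 3)), 128), "512")
  # a checkerboard of 128-px blocks resizes to exact 32-px blocks
  blocks <- matrix(c(40, 200, 200, 40), 2, 2)
  checker <- kronecker(blocks[rep(1:2, 2), rep(1:2, 2)], matrix(1, 128, 128))
  tile <- array(rep(checker, 3), dim = c(512, 512, 3))
  small <- preprocess_tiles(tile, 128)[, , 1, 1] * 255
  expected <- kronecker(blocks[rep(1:2, 2), rep(1:2, 2)], matrix(1, 32, 32))
  expect_equal(small, expected, tolerance = 1e-12)
})

test_that("training is seeded-deterministic and refuses single-class input", {
  sp <- hawkshead_spec(input_size = 32L)
  set.seed(40)
  n <- 16
  y <- rep(0:1, each = n / 2)
  x <- array(runif(32 * 32 * 3 * n), c(32, 32, 3, n))
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4, max_epochs = 3, seed = 11)
  m1 <- train_model(build_hawkshead(sp, seed = 5), x, y, x, y, cfg)
  m2 <- train_model(build_hawkshead(sp, seed = 5), x, y, x, y, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights$W1, m2$weights$W1)
  expect_equal(nrow(m1$history), 3L)
  expect_named(m1$history, c("epoch", "train_loss", "val_loss", "train_acc", "val_acc"))
  expect_error(train_model(build_hawkshead(sp, seed = 5), x, rep(1, n), x, y, cfg),
               "single class")
})

test_that("the network can overfit a small separable set (capacity sanity)", {
  sp <- hawkshead_spec(input_size = 32L)
  set.seed(50)
  n <- 64
  y <- rep(0:1, each = n / 2)
  x <- array(0, c(32, 32, 3, n))
  for (i in seq_len(n)) {
    base <- if (y[i] == 1) 0.65 else 0.35
    x[, , , i] <- pmin(pmax(base + rnorm(32 * 32 * 3, 0, 0.15), 0), 1)
  }
  m <- build_hawkshead(sp, seed = 6)
  m <- train_model(m, x, y, x, y,
                   train_config(learning_rate = 1e-3, batch_size = 8,
                                max_epochs = 30, seed = 12))
  expect_gte(tail(m$history$train_acc, 1), 0.95)
})

test_that("strong L2 regularisation shrinks the dense weights", {
  sp0 <- hawkshead_spec(input_size = 32L, l2 = 0)
  sp2 <- hawkshead_spec(input_size = 32L, l2 = 1.0)
  set.seed(60)
  n <- 24
  y <- rep(0:1, each = n / 2)
  x <- array(runif(32 * 32 * 3 * n), c(32, 32, 3, n))
  cfg <- train_config(learning_rate = 1e-3, batch_size = 8, max_epochs = 10, seed = 13)
  dense_norm <- function(m)
    sqrt(sum(m$weights$U1^2) + sum(m$weights$U2^2) + sum(m$weights$U3^2))
  m0 <- train_model(build_hawkshead(sp0, seed = 7), x, y, x, y, cfg)
  m2 <- train_model(build_hawkshead(sp2, seed = 7), x, y, x, y, cfg)
  expect_lt(dense_norm(m2), dense_norm(m0))
})

test_that("the TL head trains only itself; the extractor stays frozen", {
  ext <- toy_extractor(8)
  tl <- build_tl_head(ext, feature_dim = 8, input_size = 64)
  set.seed(70)
  n <- 40
  y <- rep(0:1, n / 2)
  x <- array(runif(64 * 64 * 3 * n), c(64, 64, 3, n))
  for (i in which(y == 1)) x[, , , i] <- x[, , , i] * 0.5 + 0.5
  feats_before <- ext(x)
  tl2 <- train_model(tl, x, y, x, y,
                     train_config(learning_rate = 5e-3, batch_size = 8,
                                  max_epochs = 10, early_stop_patience = NULL,
                                  seed = 14))
  expect_identical(ext(x), feats_before)
  expect_identical(tl2$feature_extractor, tl$feature_extractor)
  expect_false(identical(tl2$weights$U1, tl$weights$U1))
  s <- predict(tl2, x)
  expect_true(all(s >= 0 & s <= 1))
  # learnable: the head separates the shifted class above chance
  expect_gte(auroc(s, y), 0.8)
})

test_that("the TL head rejects inputs of the wrong size and early-stops", {
  ext <- toy_extractor(8)
  tl <- build_tl_head(ext, feature_dim = 8, input_size = 224)
  bad <- array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4))
  expect_error(predict(tl, bad), "224")
  # constant zero features cannot improve validation accuracy: patience 3
  # stops training at epoch 1 + 3
  zero_ext <- function(x) matrix(0, dim(x)[4], 4)
  tlz <- build_tl_head(zero_ext, feature_dim = 4, input_size = 32)
  n <- 12
  y <- rep(0:1, n / 2)
  x <- array(runif(32 * 32 * 3 * n), c(32, 32, 3, n))
  tlz <- train_model(tlz, x, y, x, y,
                     train_config(batch_size = 4, max_epochs = 20,
                                  early_stop_patience = 3L, seed = 15))
  expect_equal(nrow(tlz$history), 4L)
})

test_that("model weights survive the YAML round trip bit-for-bit in scores", {
  sp <- hawkshead_spec(input_size = 32L)
  m <- build_hawkshead(sp, seed = 8)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_model_weights(m, path)
  back <- read_model_weights(path)
  x <- array(runif(32 * 32 * 3 * 4), c(32, 32, 3, 4))
  expect_equal(predict(back, x), predict(m, x), tolerance = 1e-12)
  expect_equal(count_params(back), count_params(m))
})
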