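test_that("forward pass: shape contract, probability range, batch independence", {
  m <- build_model(model_config(base_channels = 8), seed = 31)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  p <- forward(m, x)
  expect_identical(dim(p), c(64L, 64L, 1L, 2L))
  expect_true(all(p > 0 & p < 1))

  # zeros input still strictly inside (0, 1)
  p0 <- forward(m, array(0, c(64, 64, 3, 1)))
  expect_true(all(is.finite(p0)) && all(p0 > 0 & p0 < 1))

  # identical samples in one batch give identical outputs
  xx <- array(0, c(64, 64, 3, 2))
  xx[, , , 1] <- x[, , , 1]
  xx[, , , 2] <- x[, , , 1]
  pp <- forward(m, xx)
  expect_equal(pp[, , , 1], pp[, , , 2], tolerance = 1e-12)

  # indivisible extents direct the user to predict_image
  expect_error(forward(m, array(0, c(63, 64, 3, 1))), "predict_image")
})

test_that("network depth gives depth - 1 skip connections", {
  for (depth in c(3L, 4L)) {
    cfg <- model_config(depth = depth, base_channels = 4)
    m <- build_model(cfg, seed = 32)
    expect_length(m$decoder, depth - 1L)
    expect_length(m$encoder, depth)
  }
})

test_that("parameter counting: closed forms and invariance to input size", {
  # a single 3x3 convolution 2 -> 4 with bias: 2*4*9 + 4 = 76
  cv <- mcunet:::new_conv2d_layer(3L, 2L, 4L)
  expect_identical(length(cv$w$value) + length(cv$b$value), 76L)

  m <- build_model(model_config(base_channels = 4, pooling_kernels = c(2, 3)),
                   seed = 33)
  n1 <- count_parameters(m)
  invisible(forward(m, array(0, c(32, 32, 3, 1))))
  invisible(forward(m, array(0, c(64, 64, 3, 2))))
  expect_identical(count_parameters(m), n1)
})

test_that("ablation variants are ordered and their deltas match per-module closed forms", {
  suite <- build_ablation_suite(model_config(), seed = 34)
  expect_identical(names(suite), c("backbone", "dac", "mkp", "full"))
  cnt <- vapply(suite, count_parameters, numeric(1))
  expect_true(cnt[["backbone"]] < cnt[["mkp"]])
  expect_true(cnt[["mkp"]] < cnt[["dac"]])
  expect_true(cnt[["dac"]] < cnt[["full"]])

  C <- 128  # bottleneck width at the default config
  # MKP itself: four 1x1 convs (C+1 each); it also widens the 3x3 fuse input
  expect_equal(cnt[["full"]] - cnt[["dac"]], 4 * (C + 1) + 9 * 4 * C)
  expect_equal(cnt[["mkp"]] - cnt[["backbone"]], 4 * (C + 1) + 9 * (C + 4) * C)
  # DAC: seven 3x3 and three 1x1 C->C convs, and the fuse input doubles
  expect_equal(cnt[["dac"]] - cnt[["backbone"]],
               7 * (9 * C * C + C) + 3 * (C * C + C) + 9 * C * C)

  # backbone variant contains no dilated context filters at all
  expect_null(suite$backbone$bottleneck$dac)
  expect_null(suite$backbone$bottleneck$mkp)
})

test_that("horizontally flipping the input commutes with the network when kernels are symmetric", {
  cfg <- model_config(base_channels = 4, use_dac = FALSE, use_mkp = FALSE)
  m <- build_model(cfg, seed = 35)
  # symmetrise every kernel along the width axis
  for (p in mcunet:::model_parameters(m)) {
    d <- dim(p$value)
    if (length(d) == 4L) p$value <- (p$value + p$value[, d[2]:1, , , drop = FALSE]) / 2
  }
  set.seed(36)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  xf <- x[, 64:1, , , drop = FALSE]
  p <- forward(m, x)
  pf <- forward(m, xf)[, 64:1, , , drop = FALSE]
  expect_lt(mean(abs(p - pf)), 1e-5)
})

test_that("checkpoint round-trip reproduces predictions bit-identically", {
  m <- build_model(model_config(depth = 3, base_channels = 4,
                                pooling_kernels = c(2, 3)), seed = 37)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  p1 <- forward(m, x)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_identical(forward(m2, x), p1)
  expect_identical(model_checksum(m2), model_checksum(m))
})

test_that("model config round-trips through YAML", {
  cfg <- model_config(depth = 3, base_channels = 8, use_dac = FALSE,
                      dropblock = dropblock_config(5, 0.9), fusion_mode = "sum")
  f <- tempfile(fileext = ".yaml")
  write_model_config(cfg, f)
  back <- read_model_config(f)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("training gradients point downhill: one small step reduces the loss", {
  cfg <- model_config(depth = 3, base_channels = 4, pooling_kernels = c(2, 3),
                      dropblock = dropblock_config(7, 1))  # deterministic loss
  m <- build_model(cfg, seed = 38)
  set.seed(39)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  y <- array(rbinom(32 * 32, 1, 0.2), c(32, 32, 1, 1))
  params <- mcunet:::model_parameters(m)
  tcfg <- train_config(loss = "bce")
  l1 <- mcunet:::batch_loss(m, x, y, tcfg, params)
  mcunet:::adam_step(params, 1e-4, 1L)
  l2 <- mcunet:::batch_loss(m, x, y, tcfg, params)
  expect_lt(l2, l1)
})
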