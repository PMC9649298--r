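# The differentiation tape is what makes the network trainable, so its
# gradients are verified against central finite differences on a full
# forward pass. Biases are perturbed away from zero first so no ReLU
# pre-activation sits exactly on the kink (where the one-sided derivative
# differs from the subgradient and finite differences are uninformative).

test_that("tape gradients match finite differences through the whole network", {
  cfg <- model_config(depth = 2, base_channels = 2, in_channels = 3,
                      pooling_kernels = c(1, 2),
                      dropblock = dropblock_config(3, 1))
  m <- build_model(cfg, seed = 61)
  params <- mcunet:::model_parameters(m)
  set.seed(62)
  for (p in params) p$value <- p$value + rnorm(length(p$value), 0, 0.05)
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3, 1))
  y <- array(rbinom(64, 1, 0.3), c(8, 8, 1, 1))
  lossf <- function(tp) {
    mcunet:::ag_bce_with_logits(
      mcunet:::fwd_model(m, mcunet:::new_node(x), tp, training = TRUE,
                         logits = TRUE), y, tp)
  }
  tp <- mcunet:::ag_tape()
  l <- lossf(tp)
  mcunet:::ag_backward(tp, l)
  grads <- lapply(params, function(p) p$grad)
  set.seed(63)
  eps <- 1e-5
  for (nm in names(params)) {
    p <- params[[nm]]
    for (ii in sample(length(p$value), min(2L, length(p$value)))) {
      old <- p$value[ii]
      p$value[ii] <- old + eps
      l1 <- lossf(NULL)$value
      p$value[ii] <- old - eps
      l2 <- lossf(NULL)$value
      p$value[ii] <- old
      gn <- (l1 - l2) / (2 * eps)
      expect_lt(abs(gn - grads[[nm]][ii]),
                1e-4 * max(1, abs(gn)))
    }
  }
})

test_that("soft Dice loss gradient matches finite differences", {
  set.seed(64)
  z <- array(rnorm(32), c(4, 4, 2, 1))
  t <- array(rbinom(32, 1, 0.4), c(4, 4, 2, 1))
  tp <- mcunet:::ag_tape()
  zn <- mcunet:::new_node(z, tp)
  zn$backward <- function(g) NULL  # leaf; capture grad only
  p <- mcunet:::ag_sigmoid(zn, tp)
  l <- mcunet:::ag_dice_loss(p, t, tp)
  mcunet:::ag_backward(tp, l)
  g <- zn$grad
  for (ii in sample(32, 5)) {
    old <- z[ii]
    f <- function(v) {
      zz <- z; zz[ii] <- v
      pv <- 1 / (1 + exp(-zz))
      1 - (2 * sum(pv * t) + 1) / (sum(pv) + sum(t) + 1)
    }
    gn <- (f(old + 1e-6) - f(old - 1e-6)) / 2e-6
    expect_lt(abs(gn - g[ii]), 1e-6)
  }
})

test_that("batch norm uses batch statistics in training and running statistics at inference", {
  set.seed(65)
  bnl <- mcunet:::new_bn_layer(2)
  x <- array(rnorm(6 * 6 * 2 * 2, mean = 3, sd = 2), c(6, 6, 2, 2))
  xn <- mcunet:::new_node(x)
  y <- mcunet:::ag_batchnorm(xn, bnl$gamma, bnl$beta, bnl$state,
                             training = TRUE)$value
  # normalised output: per-channel mean ~0, sd ~1
  expect_lt(max(abs(apply(y, 3, mean))), 1e-10)
  expect_lt(max(abs(apply(y, 3, sd) - 1)), 1e-2)
  # inference with fresh running stats (0/1) is an identity transform
  bn2 <- mcunet:::new_bn_layer(2)
  y2 <- mcunet:::ag_batchnorm(xn, bn2$gamma, bn2$beta, bn2$state,
                              training = FALSE)$value
  expect_equal(y2, x, tolerance = 1e-4)
})

test_that("max-pool, upsample and transposed convolution shapes and adjoints", {
  set.seed(66)
  x <- array(rnorm(7 * 7 * 2), c(7, 7, 2, 1))
  # ceil-mode pooling covers ragged borders
  p <- mcunet:::ag_maxpool(mcunet:::new_node(x), 3, 3, ceil_mode = TRUE)
  expect_identical(dim(p$value), c(3L, 3L, 2L, 1L))
  expect_equal(p$value[3, 3, 1, 1], max(x[7, 7, 1, 1]))

  u <- mcunet:::ag_upsample_nearest(p, 7, 7)
  expect_identical(dim(u$value), c(7L, 7L, 2L, 1L))

  # transposed 2x2 stride-2 convolution doubles extents; with a one-hot
  # kernel it is exactly nearest-neighbour placement
  w <- mcunet:::new_param(array(0, c(2, 2, 1, 1)))
  w$value[1, 1, 1, 1] <- 1
  xx <- array(rnorm(9), c(3, 3, 1, 1))
  y <- mcunet:::ag_conv_transpose2(mcunet:::new_node(xx), w)$value
  expect_identical(dim(y), c(6L, 6L, 1L, 1L))
  expect_equal(y[c(1, 3, 5), c(1, 3, 5), 1, 1], xx[, , 1, 1])
  expect_true(all(y[c(2, 4, 6), , , ] == 0))
})
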