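test_that("atrous convolution reduces to standard convolution at rate 1", {
  set.seed(10)
  # identity kernel: centre weight 1
  w <- array(0, c(3, 3, 1, 1))
  w[2, 2, 1, 1] <- 1
  x <- array(rnorm(36), c(6, 6, 1))
  expect_equal(atrous_conv2d(x, w, rate = 1), x, tolerance = 1e-14)
  # random kernel at rate 1 equals the explicit-loop standard convolution
  w2 <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  x2 <- array(rnorm(5 * 7 * 2), c(5, 7, 2))
  expect_equal(atrous_conv2d(x2, w2, rate = 1), brute_atrous(x2, w2, 1),
               tolerance = 1e-12)
})

test_that("1-D dilated correlation example and impulse receptive field", {
  # x = [1..5], w = [1,1,1], rate 2, zero padding 2 -> [4, 6, 9, 6, 8]
  x <- array(c(1, 2, 3, 4, 5), c(1, 5, 1))
  w <- array(0, c(3, 3, 1, 1))
  w[2, , 1, 1] <- 1
  expect_equal(as.numeric(atrous_conv2d(x, w, rate = 2)[1, , 1]),
               c(4, 6, 9, 6, 8))

  # effective receptive field of a 3x3 filter at rate 5 is 11x11
  r <- 5L; k <- 3L
  imp <- array(0, c(31, 31, 1))
  imp[16, 16, 1] <- 1
  wones <- array(1, c(3, 3, 1, 1))
  resp <- atrous_conv2d(imp, wones, rate = r)[, , 1]
  nz <- which(resp != 0, arr.ind = TRUE)
  eff <- k + (k - 1L) * (r - 1L)
  expect_equal(c(diff(range(nz[, 1])) + 1L, diff(range(nz[, 2])) + 1L),
               c(eff, eff))
  # nonzero exactly on the dilated tap lattice
  expect_identical(nrow(nz), 9L)
})

test_that("atrous convolution agrees with the brute-force oracle on random instances", {
  set.seed(11)
  for (i in 1:20) {
    H <- sample(3:8, 1); W <- sample(3:8, 1)
    Ci <- sample(1:3, 1); Co <- sample(1:2, 1)
    r <- sample(1:3, 1)
    x <- array(rnorm(H * W * Ci), c(H, W, Ci))
    w <- array(rnorm(9 * Ci * Co), c(3, 3, Ci, Co))
    b <- rnorm(Co)
    got <- atrous_conv2d(x, w, b, rate = r)
    ref <- brute_atrous(x, w, r)
    for (co in seq_len(Co)) ref[, , co] <- ref[, , co] + b[co]
    expect_lt(max(abs(got - ref)), 1e-5)
  }
  expect_error(atrous_conv2d(array(0, c(4, 4, 1)), array(0, c(2, 2, 1, 1))), "even")
})

test_that("DAC preserves shape and reduces to identity with zero branch weights", {
  set.seed(12)
  for (C in c(1L, 3L)) {
    dac <- new_dac(C)
    x <- array(rnorm(8 * 8 * C), c(8, 8, C))
    expect_identical(dim(dac_block(x, dac)), dim(x))
  }
  dac0 <- new_dac(2)
  zero_params(dac0)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_equal(dac_block(x, dac0), x, tolerance = 1e-14)
})

test_that("single-branch DAC with identity kernel doubles a non-negative input", {
  dac <- new_dac(1, branches = list(list(c(3L, 1L))))
  cv <- dac$branches[[1]][[1]]
  cv$w$value <- cv$w$value * 0
  cv$w$value[2, 2, 1, 1] <- 1
  cv$b$value <- 0
  x <- array(runif(49), c(7, 7, 1))   # non-negative so branch ReLU is inert
  expect_equal(dac_block(x, dac), 2 * x, tolerance = 1e-14)
})

test_that("MKP channel arithmetic, worked pooling example and piecewise constancy", {
  set.seed(13)
  mkp <- new_mkp(128)
  D <- array(rnorm(48 * 48 * 128), c(48, 48, 128))
  out <- mkp_block(D, mkp)
  expect_identical(dim(out), c(48L, 48L, 132L))
  expect_equal(out[, , 1:128], D, tolerance = 1e-14)  # input passes through

  # 4x4 grid 1..16 row-major, kernel 2, unit 1x1 conv -> pooled [[6,8],[14,16]]
  m1 <- new_mkp(1, kernel_sizes = 2L)
  m1$convs[[1]]$w$value[] <- 1
  m1$convs[[1]]$b$value[] <- 0
  D4 <- array(matrix(1:16, 4, 4, byrow = TRUE), c(4, 4, 1))
  pooled_up <- mkp_block(D4, m1)[, , 2]
  expect_equal(pooled_up, matrix(c(6, 6, 14, 14, 6, 6, 14, 14,
                                   8, 8, 16, 16, 8, 8, 16, 16), 4, 4),
               tolerance = 1e-14)
  # piecewise constant over the 2x2 pooling cells
  expect_true(all(pooled_up[1:2, 1:2] == pooled_up[1, 1]))

  # constant input: every appended channel is constant c (unit conv)
  mc <- new_mkp(1, kernel_sizes = c(2L, 3L))
  for (cv in mc$convs) { cv$w$value[] <- 1; cv$b$value[] <- 0 }
  Dc <- array(3.25, c(6, 6, 1))
  oc <- mkp_block(Dc, mc)
  expect_true(all(abs(oc[, , 2:3] - 3.25) < 1e-14))

  expect_error(mkp_block(array(0, c(4, 4, 1)), new_mkp(1, kernel_sizes = 6L)),
               "kernel")
})

test_that("bottleneck fusion: channel bookkeeping and composition of tested blocks", {
  set.seed(14)
  # concat width 128 + 132 = 260 before the reduction convolution
  bk <- new_bottleneck(128)
  expect_identical(dim(bk$fuse$w$value)[3], 260L)

  # small instance: output equals composing the exported operations
  bk8 <- new_bottleneck(8, kernel_sizes = c(2L, 3L))
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  got <- bottleneck_fuse(x, bk8)
  sa <- spatial_attention(x, bk8$sa)$SA
  ctx <- mkp_block(dac_block(x, bk8$dac), bk8$mkp)
  manual <- atrous_conv2d(array(c(sa, ctx), c(8, 8, 18)),
                          bk8$fuse$w$value, bk8$fuse$b$value)
  expect_equal(got, pmax(manual, 0), tolerance = 1e-10)
  expect_identical(dim(got), c(8L, 8L, 8L))

  # ablation degeneracy: no context branch -> attention-only fuse
  bk0 <- new_bottleneck(8, use_dac = FALSE, use_mkp = FALSE)
  expect_identical(dim(bk0$fuse$w$value)[3], 8L)
  expect_identical(dim(bottleneck_fuse(x, bk0)), c(8L, 8L, 8L))
})
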