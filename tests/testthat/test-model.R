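test_that("gated convolution matches its defining equation on scalar cases", {
  # Y = (X*W + b) * sigmoid(X*V + c)
  expect_equal(gated_conv(1, w = 2, v = 0, b = 0, c = 0), 2 * 0.5) # 2*sigma(0)
  expect_equal(gated_conv(c(1, 2, 3), w = 0, v = 0, b = 0, c = 0),
               rep(0, 3))
  # gate saturation: c large -> gate ~ 1, Y -> X*W + b
  x <- c(0.3, -1.2, 2.5)
  expect_equal(gated_conv(x, w = 2, v = 0, b = 0.5, c = 30),
               2 * x + 0.5, tolerance = 1e-9)
})

test_that("gated convolution output is bounded by its feature path", {
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(30)
    w <- rnorm(3); v <- rnorm(3); b <- rnorm(1); c <- rnorm(1)
    y <- gated_conv(x, w, v, b, c, padding = "same")
    feat <- brute_conv_same(x, w) + b
    expect_true(all(abs(y) <= abs(feat) + 1e-12))
  }
})

test_that("dilated convolution follows the tap-spacing formula", {
  # valid positions, K = 2 causal taps spaced l = 2: F(x) + F(x+2)
  expect_equal(dilated_conv(c(1, 2, 3, 4), c(1, 1), l = 2), c(4, 6))
  # l = 1 equals standard convolution
  set.seed(22)
  f <- rnorm(50)
  k <- rnorm(5)
  expect_equal(dilated_conv(f, k, l = 1, padding = "same"),
               brute_conv_same(f, k, 1L))
  # centred delta kernel is the identity for any dilation
  for (l in c(1, 2, 5))
    expect_equal(dilated_conv(f, c(0, 1, 0), l = l, padding = "same"), f)
  expect_error(dilated_conv(f, k, l = 0), "positive")
})

test_that("dilated convolution equals the brute-force oracle over random cases", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    K <- sample(c(1, 3, 5, 7, 11), 1)
    l <- sample(1:5, 1)
    f <- rnorm(n)
    k <- rnorm(K)
    expect_equal(dilated_conv(f, k, l = l, padding = "same"),
                 brute_conv_same(f, k, l), tolerance = 1e-6)
  }
})

test_that("compiled convolution engine matches the R convolution on multichannel input", {
  set.seed(24)
  for (i in 1:20) {
    C <- sample(1:4, 1); Cout <- sample(1:3, 1)
    K <- sample(c(1, 3, 5), 1); d <- sample(1:3, 1)
    W <- sample(12:30, 1); B <- sample(1:3, 1)
    X <- matrix(rnorm(C * W * B), C) # position-major: col = w*B + b
    Wt <- matrix(rnorm(Cout * K * C), Cout)
    bias <- rnorm(Cout)
    Y <- hdgsnet:::.hdgs_conv_same_cpp(X, Wt, bias, K, d, B, W)
    # oracle: per output channel / lane, sum over in-channels of 1-D convs
    for (co in seq_len(Cout)) for (b in seq_len(B)) {
      cols <- (seq_len(W) - 1L) * B + b
      acc <- rep(bias[co], W)
      for (ci in seq_len(C)) {
        kern <- Wt[co, (seq_len(K) - 1L) * C + ci]
        acc <- acc + brute_conv_same(X[ci, cols], kern, d)
      }
      expect_equal(Y[co, cols], acc, tolerance = 1e-5)
    }
  }
})

test_that("separable parameter formulas and the full-convolution comparison hold", {
  p <- separable_params(3, 2, 4)
  expect_equal(p$depthwise_2d, 18) # K^2 * C_in
  expect_equal(p$pointwise, 8)     # C_in * C_out
  expect_equal(p$depthwise_1d, 6)  # K * C_in
  expect_equal(p$total_1d, 14)
  expect_equal(p$full_1d, 24)
  expect_true(p$total_1d < p$full_1d)

  # K = 1: no saving, separable total equals pointwise plus the 1-channel mix
  p1 <- separable_params(1, 8, 16)
  expect_equal(p1$total_1d, p1$depthwise_1d + p1$pointwise)
  expect_equal(p1$full_1d, p1$pointwise)

  # identity grid: the formulas hold for all K, C_in, C_out combinations
  grid <- expand.grid(K = 1:8, C_in = c(1, 2, 16, 64), C_out = c(1, 3, 64))
  g <- separable_params(grid$K, grid$C_in, grid$C_out)
  expect_equal(g$depthwise_2d, grid$K^2 * grid$C_in)
  expect_equal(g$pointwise, grid$C_in * grid$C_out)
  expect_equal(g$total_2d, grid$K^2 * grid$C_in + grid$C_in * grid$C_out)
  expect_equal(g$full_2d, grid$K^2 * grid$C_in * grid$C_out)
  saving <- g$total_1d < g$full_1d
  expect_equal(saving, grid$K > 1 & grid$C_out > 1)
})

test_that("scaled configuration preserves the width trace and divides channels", {
  m <- hdgs_build(hdgs_config(scale = 8))
  tr <- shape_trace(m)
  expect_equal(tr$width, c(146L, 48L, 16L, 5L, 1L))
  expect_equal(tr$channels, c(1L, 80L, 80L, 64L, 24L))
  expect_equal(count_parameters(m), reference_param_count(8))
  expect_error(hdgs_config(scale = 7), "divide")
})

test_that("parameter manifest matches the closed-form sum and a hand-counted branch", {
  m <- hdgs_build(hdgs_config(scale = 8))
  mf <- parameter_manifest(m)
  expect_equal(sum(mf$count), count_parameters(m))

  # single gated conv branch, K = 1, 1 -> 128 channels with biases:
  # 2*(1*1*128) weights + 2*128 biases = 512
  cfg <- tiny_config(channels = 128L)
  cfg$modules <- list(list(branches = list(hdgs_branch("gc", 1L, 1L, 128L))))
  mg <- hdgs_build(cfg)
  mfg <- parameter_manifest(mg)
  branch <- mfg[grepl("branch1", mfg$parameter), ]
  expect_equal(sum(branch$count), 512)
})

test_that("forward pass honours head contracts, empty input and shape checks", {
  feats <- random_features(2, seed = 31)
  mr <- hdgs_build(tiny_config("regression"))
  pr <- predict(mr, feats)
  expect_length(pr, 2L)
  expect_true(all(pr >= 0))

  mc <- hdgs_build(tiny_config("classification"))
  pc <- predict(mc, feats)
  expect_true(all(pc >= 0 & pc <= 1))

  expect_length(predict(mr, feats[0, , , drop = FALSE]), 0L)
  expect_error(predict(mr, array(0L, c(2, 16, 100))), "expects")

  # evaluation-mode forward is deterministic (dropout off)
  expect_identical(predict(mr, feats), predict(mr, feats))
})

test_that("builds fail with the stage name when pooling collapses the width", {
  cfg <- tiny_config()
  cfg$modules <- rep(cfg$modules, 6) # width trace 146,48,16,5,1,<3 -> error
  expect_error(hdgs_build(cfg), "module")
  expect_error(hdgs_build(cfg), "width")
})

test_that("weights survive a save/restore round trip through R", {
  m1 <- hdgs_build(tiny_config(seed = 5))
  m2 <- hdgs_build(tiny_config(seed = 6))
  feats <- random_features(3, seed = 32)
  expect_false(isTRUE(all.equal(predict(m1, feats), predict(m2, feats))))
  hdgs_set_weights(m2, hdgs_weights(m1))
  expect_identical(predict(m1, feats), predict(m2, feats))
  w <- hdgs_weights(m1)
  w$trainable[[1]] <- NULL
  expect_error(hdgs_set_weights(m2, w), "lacks")
})
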