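test_that("kernel size mapping follows the adopted channel-to-k rule", {
  expect_identical(kernel_size_from_channels(64), 3L)
  expect_identical(kernel_size_from_channels(512), 5L)
  expect_identical(kernel_size_from_channels(1), 1L)
  expect_identical(kernel_size_from_channels(2), 1L)
  for (C in c(3, 8, 16, 100, 128, 256, 1024)) {
    k <- kernel_size_from_channels(C)
    expect_true(k %% 2 == 1 && k >= 1 && k <= C)
  }
  expect_error(kernel_size_from_channels(0), "positive")
})

test_that("global descriptor is spatial mean plus max per channel", {
  expect_equal(global_descriptor(array(2, c(3, 5, 4))), rep(4, 3))
  expect_equal(global_descriptor(array(3, c(2, 1, 1))), rep(6, 2))
  x <- array(0, c(1, 2, 2))
  x[1, , ] <- c(1, 3, 5, 7)
  expect_equal(global_descriptor(x), 4 + 7)
  expect_error(global_descriptor(array(0, c(2, 0, 3))), "spatial")
})

test_that("attention weights are a sigmoid-gated zero-padded 1D convolution", {
  g <- c(1, 2, 3)
  expect_equal(attention_weights(g, band_kernel(c(0, 0, 0))), rep(0.5, 3))
  # degenerate k = 1 band: elementwise sigmoid scaling
  w <- 0.7
  expect_equal(attention_weights(g, band_kernel(w)), 1 / (1 + exp(-w * g)))
  # hand convolution: inner position of (1,2,3) with kernel (.1,.2,.3)
  om <- attention_weights(g, band_kernel(c(0.1, 0.2, 0.3)))
  expect_equal(om[2], 1 / (1 + exp(-(0.1 * 1 + 0.2 * 2 + 0.3 * 3))))
  # zero padding at the ends
  expect_equal(om[1], 1 / (1 + exp(-(0.2 * 1 + 0.3 * 2))))
  expect_true(all(om > 0 & om < 1))
  expect_error(band_kernel(c(1, 2)), "odd")
})

test_that("applying attention scales channels and preserves shape", {
  x <- array(stats::rnorm(4 * 3 * 3), c(4, 3, 3))
  expect_equal(apply_attention(x, rep(1, 4)), x)
  expect_equal(apply_attention(x, rep(0, 4)), array(0, dim(x)))
  w <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(apply_attention(2 * x, w), 2 * apply_attention(x, w))
  expect_equal(apply_attention(x, w)[2, , ], 0.4 * x[2, , ])
  expect_error(apply_attention(x, c(1, 2)), "channel count")
})

test_that("descriptor and k=1 attention are permutation-equivariant across channels", {
  set.seed(3)
  x <- array(stats::rnorm(5 * 4 * 4), c(5, 4, 4))
  p <- sample(5)
  expect_equal(global_descriptor(x[p, , ]), global_descriptor(x)[p])
  g <- global_descriptor(x)
  kern <- band_kernel(0.9)
  expect_equal(attention_weights(g[p], kern), attention_weights(g, kern)[p])
})

test_that("a zero-kernel attention module halves a conv+BN toy block's output", {
  # single conv -> BN -> attention with all kernel weights zero: sigma(0)=0.5,
  # so the attended output is the plain output scaled by 0.5
  set.seed(11)
  conv <- cacpnet:::new_conv(3L, 6L, 3L, 1L, 1L)
  bn <- cacpnet:::new_bn(6L)
  att <- cacpnet:::new_attention(6L, 3L)
  att$w <- rep(0, 3)
  fm <- cacpnet:::images_to_fmap(random_images(2, size = 8, seed = 12))
  plain <- cacpnet:::bn_fwd(bn, cacpnet:::conv_fwd(conv, fm))
  gated <- cacpnet:::att_fwd(att, plain)
  expect_equal(gated$x, 0.5 * plain$x)
})

test_that("attachment keeps every forward shape and adds only kernel parameters", {
  spec <- toy_spec()
  plain <- build_model(spec, seed = 1)
  attended <- attach_attention(plain, seed = 2)
  imgs <- random_images(2, seed = 3)
  expect_equal(dim(predict_batch(attended, imgs, type = "logit")),
               dim(predict_batch(plain, imgs, type = "logit")))
  am <- attention_modules(attended$spec)
  expect_equal(count_parameters(attended) - count_parameters(plain),
               sum(am$k))
  # one module per 3x3 conv: stem + 2 per block
  expect_equal(nrow(am), 1L + 2L * sum(spec$blocks_per_stage))
})
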