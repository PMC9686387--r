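test_that("the default 5-class spec reproduces the standard 18-layer design", {
  spec <- spec_peanut()
  net <- build_model(spec, seed = 1)
  # three routes: actual weight arrays, closed-form profiler, and the
  # independent enumeration oracle
  expect_identical(count_parameters(net), 11179077)
  expect_identical(enumerate_params(spec), 11179077)
  expect_equal(profile_model(spec)$params, 11179077)
})

test_that("parameter count matches the enumeration oracle on random specs", {
  set.seed(42)
  for (i in 1:4) {
    spec <- arch_spec(
      stem_channels = sample(3:8, 1),
      stage_widths = sample(4:12, 4, replace = TRUE),
      blocks_per_stage = sample(1:3, 4, replace = TRUE),
      num_classes = sample(2:6, 1),
      input_size = 32L,
      attention_enabled = i %% 2 == 0
    )
    net <- build_model(spec, seed = i)
    expect_equal(count_parameters(net), enumerate_params(spec))
    expect_equal(profile_model(spec)$params, enumerate_params(spec))
  }
})

test_that("head contract: output is N x num_classes and only the head scales with classes", {
  spec <- toy_spec(classes = 4L)
  net <- build_model(spec, seed = 1)
  z <- predict_batch(net, random_images(3), type = "logit")
  expect_equal(dim(z), c(3L, 4L))
  spec7 <- toy_spec(classes = 7L)
  delta <- count_parameters(build_model(spec7, seed = 1)) -
    count_parameters(net)
  expect_equal(delta, spec$stage_widths[4] * 3 + 3)  # 3 extra classes
})

test_that("forward pass is deterministic given fixed weights and input", {
  net <- build_model(toy_spec(attention = TRUE), seed = 5)
  imgs <- random_images(2, seed = 9)
  expect_identical(predict_batch(net, imgs), predict_batch(net, imgs))
})

test_that("disabling attention changes parameters by exactly the kernel sizes", {
  plain <- build_model(spec_peanut(), seed = 1)
  attended <- attach_attention(plain, seed = 2)
  am <- attention_modules(attended$spec)
  expect_equal(nrow(am), 17L)
  expect_equal(count_parameters(attended) - count_parameters(plain),
               sum(am$k))
  expect_lte(sum(am$k), 100)
})

test_that("specs round-trip losslessly through their serialized form", {
  specs <- list(
    spec_peanut(),
    spec_plantvillage(attention_enabled = TRUE),
    arch_spec(stage_widths = c(64L, 116L, 205L, 359L), num_classes = 5L),
    arch_spec(stem_channels = 6L, stage_widths = c(6L, 7L, 9L, 11L),
              blocks_per_stage = c(2L, 1L, 3L, 2L), num_classes = 2L,
              input_size = 48L, attention_enabled = TRUE,
              block_inner_widths = list(c(5L, 6L), 7L, c(8L, 9L, 7L),
                                        c(10L, 11L)))
  )
  for (spec in specs) {
    expect_equal(parse_spec(serialize_spec(spec)), spec)
  }
})

test_that("malformed spec text and invalid fields raise errors naming the field", {
  txt <- serialize_spec(spec_peanut())
  x <- jsonlite::fromJSON(txt)
  x$num_classes <- NULL
  expect_error(parse_spec(jsonlite::toJSON(x, auto_unbox = TRUE)),
               "num_classes")
  expect_error(parse_spec("{not json"), "malformed")
  expect_error(arch_spec(stage_widths = c(64, 128, 256)), "stage_widths")
  expect_error(arch_spec(num_classes = 0), "num_classes")
  expect_error(arch_spec(stage_strides = c(1, 2, 3, 2)), "stage_strides")
  expect_error(arch_spec(input_size = 16), "input_size")
})

test_that("checkpoints reload through their sidecar and reproduce outputs", {
  net <- build_model(toy_spec(attention = TRUE), seed = 3)
  imgs <- random_images(2, seed = 4)
  path <- file.path(tempdir(), "toy-ckpt.rds")
  save_checkpoint(net, path)
  expect_true(file.exists(paste0(path, ".json")))
  net2 <- load_checkpoint(path)
  expect_equal(predict_batch(net2, imgs), predict_batch(net, imgs))
  file.remove(paste0(path, ".json"))
  expect_error(load_checkpoint(path), "sidecar")
})
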