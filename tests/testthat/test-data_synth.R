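small_cfg <- function(n = 4L, size = 32L, seed = 1L, ...) {
  synth_config(n_per_class = n, image_size = size, seed = seed, ...)
}

test_that("generation is deterministic given the seed and seed-sensitive", {
  a <- generate_synthetic_dataset(small_cfg())
  b <- generate_synthetic_dataset(small_cfg())
  expect_identical(a$images, b$images)
  expect_identical(a$labels, b$labels)
  # byte-identical on disk too
  fa <- tempfile(fileext = ".png"); fb <- tempfile(fileext = ".png")
  png::writePNG(a$images[[1]], fa); png::writePNG(b$images[[1]], fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  d <- generate_synthetic_dataset(small_cfg(seed = 2L))
  expect_false(identical(a$images[[1]], d$images[[1]]))
})

test_that("the generator produces the requested classes and counts", {
  set <- generate_synthetic_dataset(small_cfg(n = 3L))
  expect_equal(length(set), 15L)
  expect_equal(unname(table(set$labels)[set$classes]), rep(3L, 5L),
               ignore_attr = TRUE)
  expect_equal(dim(set$images[[1]]), c(32L, 32L, 3L))
  expect_true(all(vapply(set$images, function(x) all(x >= 0 & x <= 1),
                         logical(1))))
  expect_error(synth_config(classes = c("HL", "XX")), "unknown class")
  expect_error(synth_config(n_per_class = 0), "n_per_class")
})

test_that("splitting is stratified 4:1, disjoint and seed-reproducible", {
  set <- generate_synthetic_dataset(small_cfg(n = 300L, size = 32L))
  sp <- split_dataset(set, seed = 3L)
  expect_equal(length(sp$train), 1200L)
  expect_equal(length(sp$test), 300L)
  expect_equal(unname(table(sp$test$labels)), rep(60L, 5L),
               ignore_attr = TRUE)
  # disjointness via image identity
  key <- function(img) paste(img[1, 1, ], img[16, 16, ], collapse = ",")
  expect_length(intersect(vapply(sp$train$images, key, character(1)),
                          vapply(sp$test$images, key, character(1))), 0L)
  sp2 <- split_dataset(set, seed = 3L)
  expect_identical(sp$test$labels, sp2$test$labels)
  expect_identical(sp$test$images[[5]], sp2$test$images[[5]])
  tiny <- leaf_image_set(set$images[1:4], set$labels[1:4], set$classes)
  expect_error(split_dataset(tiny), "at least 5")
})

test_that("amplification is exactly five-fold with the documented transforms", {
  set <- generate_synthetic_dataset(small_cfg(n = 2L))
  amp <- amplify(set)
  expect_equal(length(amp), 5L * length(set))
  expect_equal(unname(table(amp$labels)), rep(10L, 5L), ignore_attr = TRUE)
  expect_equal(length(amplify(set, vertical_flip = TRUE)), 6L * length(set))
  img <- set$images[[1]]
  r90 <- cacpnet:::rot90cw(img)
  # rotation group: four quarter turns are the identity
  expect_equal(cacpnet:::rot90cw(cacpnet:::rot90cw(cacpnet:::rot90cw(r90))),
               img)
  # horizontal flip is an involution
  expect_equal(cacpnet:::flip_h(cacpnet:::flip_h(img)), img)
  # the five amplified variants of one image are the expected transforms
  expect_identical(amp$images[[1]], img)
  expect_equal(amp$images[[2]], r90)
  expect_equal(amp$images[[5]], cacpnet:::flip_h(img))
})

test_that("ImageFolder round trip preserves images and layout", {
  set <- generate_synthetic_dataset(small_cfg(n = 2L))
  root <- file.path(tempdir(), "synth-folder")
  unlink(root, recursive = TRUE)
  manifest <- write_dataset(set, root)
  expect_setequal(list.dirs(root, recursive = FALSE, full.names = FALSE),
                  set$classes)
  expect_equal(nrow(utils::read.csv(file.path(root, "manifest.csv"))),
               length(set))
  back <- load_standardize(root, size = 32L, method = "unit")
  expect_equal(length(back), length(set))
  # same class -> same images (order within class is file order)
  hl_orig <- set$images[set$labels == "HL"]
  hl_back <- back$images[back$labels == "HL"]
  expect_equal(hl_back, hl_orig, tolerance = 1e-9)
})

test_that("loading standardizes size and channel statistics invertibly", {
  set <- generate_synthetic_dataset(small_cfg(n = 2L, size = 40L))
  out <- load_standardize(set, size = 32L)
  expect_equal(dim(out$images[[1]]), c(32L, 32L, 3L))
  stats <- attr(out, "stats")
  # standardized training data has ~zero mean and unit variance per channel
  st <- channel_stats(out)
  expect_equal(st$mean, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(st$sd, c(1, 1, 1), tolerance = 1e-6)
  # de-normalization recovers the resized inputs to float precision
  rec <- destandardize(out, stats)
  plain <- load_standardize(set, size = 32L, method = "unit")
  expect_equal(rec$images, plain$images, tolerance = 1e-12)
  # an already-sized image passes through the resize untouched
  expect_identical(cacpnet:::resize_image(set$images[[1]], 40L),
                   set$images[[1]])
})
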