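#' Synthetic leaf-disease generator configuration
#'
#' The generator emulates five visually separable peanut-leaf categories on a
#' green elliptical leaf over a textured soil-like background: `HL` (healthy,
#' no lesions), `RD` (rust: many small orange specks), `SD` (scorch: browned,
#' darkened leaf margin), `SD+RD` (both), and `LSD` (leaf spot: a few large
#' brown circular lesions with lighter halos). Geometry and colors are
#' jittered per image; everything is driven by one seed.
#'
#' @param classes Subset of `c("HL","SD","RD","SD+RD","LSD")`.
#' @param n_per_class Images per class.
#' @param image_size Square image side in pixels (>= 32; 64 is the desk-scale
#'   default, 224 matches field resolution).
#' @param seed Integer seed; output depends only on the configuration.
#' @param lesion Optional overrides: `rust_n` (range of speck counts),
#'   `rust_radius`, `spot_n`, `spot_radius` (fractions of image size),
#'   `margin_band` (scorch band width as a fraction of the leaf radius).
#' @return A `synth_config`.
#' @export
synth_config <- function(classes = c("HL", "SD", "RD", "SD+RD", "LSD"),
                         n_per_class = 200L, image_size = 64L, seed = 1L,
                         lesion = list()) {
  known <- c("HL", "SD", "RD", "SD+RD", "LSD")
  bad <- setdiff(classes, known)
  if (length(bad)) {
    stop("unknown class(es): ", paste(bad, collapse = ", "),
         "; known classes are ", paste(known, collapse = ", "), call. = FALSE)
  }
  if (n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (image_size < 32L) stop("image_size must be >= 32", call. = FALSE)
  defaults <- list(rust_n = c(25L, 60L), rust_radius = c(0.012, 0.03),
                   spot_n = c(2L, 5L), spot_radius = c(0.06, 0.12),
                   margin_band = 0.18)
  lesion <- utils::modifyList(defaults, lesion)
  structure(list(classes = classes, n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), seed = as.integer(seed),
                 lesion = lesion),
            class = "synth_config")
}

# squared normalized elliptical radius of every pixel: <= 1 inside the leaf
ellipse_r2 <- function(S, cx, cy, a, b, theta) {
  x <- matrix(seq_len(S), S, S) - cx          # rows = h
  y <- matrix(seq_len(S), S, S, byrow = TRUE) - cy
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  (u / a)^2 + (v / b)^2
}

disc_mask <- function(S, cx, cy, r) {
  x <- matrix(seq_len(S), S, S) - cx
  y <- matrix(seq_len(S), S, S, byrow = TRUE) - cy
  x^2 + y^2 <= r^2
}

# coarse smooth noise field in [-1, 1], bilinearly upsampled from a g x g grid
smooth_noise <- function(S, g = 8L) {
  coarse <- matrix(stats::runif(g * g, -1, 1), g, g)
  at <- seq(1, g, length.out = S)
  i0 <- pmin(floor(at), g - 1L); fr <- at - i0
  rows <- coarse[i0, , drop = FALSE] * (1 - fr) +
    coarse[i0 + 1L, , drop = FALSE] * fr
  rows[, i0, drop = FALSE] * rep(1 - fr, each = S) +
    rows[, i0 + 1L, drop = FALSE] * rep(fr, each = S)
}

set_rgb <- function(img, mask, rgb) {
  for (c in 1:3) {
    ch <- img[, , c]
    ch[mask] <- rgb[c]
    img[, , c] <- ch
  }
  img
}

synth_image <- function(cls, S, lesion) {
  runif1 <- function(lo, hi) stats::runif(1, lo, hi)
  img <- array(0, c(S, S, 3))
  # textured background
  bg <- c(0.45, 0.38, 0.28) + stats::rnorm(3, 0, 0.03)
  noise <- smooth_noise(S) * 0.06 +
    matrix(stats::runif(S * S, -0.02, 0.02), S, S)
  for (c in 1:3) img[, , c] <- pmin(pmax(bg[c] + noise, 0), 1)
  # leaf ellipse
  cx <- S / 2 + runif1(-S * 0.04, S * 0.04)
  cy <- S / 2 + runif1(-S * 0.04, S * 0.04)
  a <- S * runif1(0.30, 0.38)
  b <- S * runif1(0.20, 0.28)
  theta <- runif1(0, pi)
  r2 <- ellipse_r2(S, cx, cy, a, b, theta)
  leaf <- r2 <= 1
  green <- c(0.18, 0.52, 0.16) + stats::rnorm(3, 0, 0.03)
  shade <- 1 - 0.25 * r2      # brighter center
  leaf_tex <- smooth_noise(S) * 0.04
  for (c in 1:3) {
    ch <- img[, , c]
    ch[leaf] <- pmin(pmax(green[c] * shade[leaf] + leaf_tex[leaf], 0), 1)
    img[, , c] <- ch
  }
  inside <- which(r2 <= 0.85, arr.ind = TRUE)
  has_sd <- cls %in% c("SD", "SD+RD")
  has_rd <- cls %in% c("RD", "SD+RD")
  if (has_sd) {
    band <- lesion$margin_band * runif1(0.8, 1.2)
    margin <- leaf & r2 >= (1 - band)^2
    brown <- c(0.36, 0.22, 0.08) + stats::rnorm(3, 0, 0.02)
    img <- set_rgb(img, margin, brown)
  }
  if (has_rd) {
    n <- sample(seq(lesion$rust_n[1], lesion$rust_n[2]), 1)
    pick <- inside[sample(nrow(inside), min(n, nrow(inside))), , drop = FALSE]
    orange <- c(0.82, 0.45, 0.10)
    for (i in seq_len(nrow(pick))) {
      r <- S * runif1(lesion$rust_radius[1], lesion$rust_radius[2])
      m <- disc_mask(S, pick[i, 1], pick[i, 2], max(r, 1))
      img <- set_rgb(img, m, orange + stats::rnorm(3, 0, 0.04))
    }
  }
  if (cls == "LSD") {
    n <- sample(seq(lesion$spot_n[1], lesion$spot_n[2]), 1)
    pick <- inside[sample(nrow(inside), min(n, nrow(inside))), , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      r <- S * runif1(lesion$spot_radius[1], lesion$spot_radius[2])
      halo <- disc_mask(S, pick[i, 1], pick[i, 2], r * 1.45) & leaf
      core <- disc_mask(S, pick[i, 1], pick[i, 2], r)
      img <- set_rgb(img, halo, c(0.72, 0.62, 0.38) + stats::rnorm(3, 0, 0.03))
      img <- set_rgb(img, core, c(0.42, 0.26, 0.10) + stats::rnorm(3, 0, 0.03))
    }
  }
  # quantize to the 8-bit grid so disk round trips are lossless
  round(pmin(pmax(img, 0), 1) * 255) / 255
}

#' Generate a synthetic labeled leaf-disease image set
#'
#' Deterministic given the configuration: the same `synth_config` always
#' produces byte-identical images.
#'
#' @param cfg A [synth_config()].
#' @return A `leaf_image_set`: list of H x W x 3 arrays in `[0,1]`, a label
#'   vector, and the class list.
#' @examples
#' set <- generate_synthetic_dataset(synth_config(n_per_class = 2))
#' length(set$images)  # 10
#' @export
generate_synthetic_dataset <- function(cfg) {
  if (!inherits(cfg, "synth_config")) stop("cfg must be a synth_config")
  with_seed(cfg$seed, {
    n <- cfg$n_per_class * length(cfg$classes)
    images <- vector("list", n)
    labels <- character(n)
    i <- 0L
    for (cls in cfg$classes) {
      for (j in seq_len(cfg$n_per_class)) {
        i <- i + 1L
        images[[i]] <- synth_image(cls, cfg$image_size, cfg$lesion)
        labels[i] <- cls
      }
    }
    leaf_image_set(images, labels, cfg$classes)
  })
}

#' Construct a labeled image set
#'
#' @param images List of H x W x 3 numeric arrays.
#' @param labels Character vector of class labels, one per image.
#' @param classes Class list (defaults to the sorted unique labels).
#' @return A `leaf_image_set`.
#' @export
leaf_image_set <- function(images, labels, classes = sort(unique(labels))) {
  if (length(images) != length(labels)) {
    stop("images and labels lengths differ", call. = FALSE)
  }
  if (!all(labels %in% classes)) {
    stop("labels outside the class list: ",
         paste(setdiff(labels, classes), collapse = ", "), call. = FALSE)
  }
  structure(list(images = images, labels = labels, classes = classes),
            class = "leaf_image_set")
}

#' @export
print.leaf_image_set <- function(x, ...) {
  d <- if (length(x$images)) dim(x$images[[1]]) else c(NA, NA, NA)
  cat(sprintf("<leaf_image_set> %d images (%dx%d), %d classes\n",
              length(x$images), d[1], d[2], length(x$classes)))
  print(table(x$labels))
  invisible(x)
}

#' @export
length.leaf_image_set <- function(x) length(x$images)

subset_set <- function(set, idx) {
  leaf_image_set(set$images[idx], set$labels[idx], set$classes)
}

#' Stratified train/test split
#'
#' Randomly splits each class with a train:test ratio of 4:1 (test size
#' `round(n/5)` per class by default). Deterministic given the seed; train and
#' test are disjoint.
#'
#' @param set A `leaf_image_set`.
#' @param test_fraction Per-class test fraction (default 0.2, i.e. 4:1).
#' @param seed Integer seed.
#' @return `list(train = ..., test = ...)`.
#' @export
split_dataset <- function(set, test_fraction = 0.2, seed = 1L) {
  counts <- table(set$labels)
  if (any(counts < 5L)) {
    stop("every class needs at least 5 records to split 4:1; got: ",
         paste(names(counts)[counts < 5], collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    test_idx <- integer(0)
    for (cls in set$classes) {
      idx <- which(set$labels == cls)
      n_test <- round(length(idx) * test_fraction)
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    list(train = subset_set(set, setdiff(seq_along(set$labels), test_idx)),
         test = subset_set(set, sort(test_idx)))
  })
}

rot90cw <- function(img) {
  # 90 degrees clockwise, per channel
  out <- array(0, c(dim(img)[2], dim(img)[1], 3))
  for (c in 1:3) out[, , c] <- t(img[rev(seq_len(dim(img)[1])), , c])
  out
}

flip_h <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
flip_v <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]

#' Rotation/flip amplification of a training set
#'
#' Each image yields itself plus its 90, 180 and 270 degree rotations and its
#' horizontal flip — exactly a five-fold amplification (1500 originals become
#' 7500), labels preserved. A vertical flip is available behind a flag for a
#' six-fold variant. Only ever applied to training data.
#'
#' @param train A `leaf_image_set`.
#' @param vertical_flip Also include the vertical flip (x6 amplification)?
#' @return The amplified `leaf_image_set`.
#' @export
amplify <- function(train, vertical_flip = FALSE) {
  out_imgs <- list()
  out_labels <- character(0)
  for (i in seq_along(train$images)) {
    img <- train$images[[i]]
    r90 <- rot90cw(img)
    r180 <- rot90cw(r90)
    r270 <- rot90cw(r180)
    block <- list(img, r90, r180, r270, flip_h(img))
    if (vertical_flip) block <- c(block, list(flip_v(img)))
    out_imgs <- c(out_imgs, block)
    out_labels <- c(out_labels, rep(train$labels[i], length(block)))
  }
  leaf_image_set(out_imgs, out_labels, train$classes)
}

#' Write an image set as an ImageFolder directory
#'
#' Creates `root/<class>/<index>.png` plus a `manifest.csv` with columns
#' `path,label,split`.
#'
#' @param set A `leaf_image_set`.
#' @param dir Output directory.
#' @param split Split tag recorded in the manifest.
#' @return The manifest data.frame, invisibly.
#' @export
write_dataset <- function(set, dir, split = "train") {
  rows <- vector("list", length(set$images))
  counters <- stats::setNames(integer(length(set$classes)), set$classes)
  for (i in seq_along(set$images)) {
    cls <- set$labels[i]
    cls_dir <- file.path(dir, cls)
    dir.create(cls_dir, recursive = TRUE, showWarnings = FALSE)
    counters[cls] <- counters[cls] + 1L
    path <- file.path(cls_dir, sprintf("%05d.png", counters[cls]))
    png::writePNG(set$images[[i]], path)
    rows[[i]] <- data.frame(path = path, label = cls, split = split)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

read_one_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (requireNamespace("EBImage", quietly = TRUE)) {
    img <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(img)) == 3L) img <- aperm(img, c(2, 1, 3))  # x,y -> h,w
  } else {
    stop("cannot decode '", path, "': only PNG supported without EBImage")
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

# bilinear resize of an H x W x 3 array to size x size
resize_image <- function(img, size) {
  if (dim(img)[1] == size && dim(img)[2] == size) return(img)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    # EBImage uses x,y (= w,h) order
    x <- EBImage::resize(EBImage::Image(aperm(img, c(2, 1, 3)),
                                        colormode = "Color"),
                         w = size, h = size)
    return(aperm(EBImage::imageData(x), c(2, 1, 3)))
  }
  bilinear_resize(img, size, size)
}

bilinear_resize <- function(img, out_h, out_w) {
  H <- dim(img)[1]; W <- dim(img)[2]
  at_h <- (seq_len(out_h) - 0.5) * H / out_h + 0.5
  at_w <- (seq_len(out_w) - 0.5) * W / out_w + 0.5
  h0 <- pmin(pmax(floor(at_h), 1L), H); fh <- pmin(pmax(at_h - h0, 0), 1)
  w0 <- pmin(pmax(floor(at_w), 1L), W); fw <- pmin(pmax(at_w - w0, 0), 1)
  h1 <- pmin(h0 + 1L, H); w1 <- pmin(w0 + 1L, W)
  out <- array(0, c(out_h, out_w, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) {
    ch <- matrix(img[, , c], H, W)
    top <- ch[h0, w0, drop = FALSE] * (1 - fh) +
      ch[h1, w0, drop = FALSE] * fh
    bot <- ch[h0, w1, drop = FALSE] * (1 - fh) +
      ch[h1, w1, drop = FALSE] * fh
    out[, , c] <- top * rep(1 - fw, each = out_h) + bot * rep(fw, each = out_h)
  }
  out
}

#' Load an ImageFolder directory and standardize it
#'
#' Reads `root/<class>/*.png|jpg` (undecodable files are skipped with a
#' warning; an empty class errors), bilinearly resizes every image to
#' `size x size`, scales to `[0,1]`, and optionally standardizes per channel.
#' Passing an in-memory `leaf_image_set` skips the reading step.
#'
#' @param path_or_set Directory in class-per-subdirectory layout, or a
#'   `leaf_image_set`.
#' @param size Target square resolution (default 224).
#' @param method `"dataset"`: subtract/divide per-channel mean/sd (computed
#'   from this set unless `stats` is supplied — supply the training-set stats
#'   when standardizing test data); `"unit"`: leave values in `[0,1]`.
#' @param stats Optional `list(mean=, sd=)` of length-3 channel statistics.
#' @return A standardized `leaf_image_set` with attribute `"stats"`.
#' @export
load_standardize <- function(path_or_set, size = 224L,
                             method = c("dataset", "unit"), stats = NULL) {
  method <- match.arg(method)
  set <- if (inherits(path_or_set, "leaf_image_set")) {
    path_or_set
  } else {
    load_image_folder(path_or_set)
  }
  set$images <- lapply(set$images, resize_image, size = size)
  if (method == "unit") {
    attr(set, "stats") <- list(mean = c(0, 0, 0), sd = c(1, 1, 1))
    return(set)
  }
  stats <- stats %||% channel_stats(set)
  standardize(set, stats)
}

#' @rdname load_standardize
#' @export
load_image_folder <- function(path_or_set) {
  root <- path_or_set
  if (!dir.exists(root)) stop("directory '", root, "' not found")
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (!length(classes)) stop("no class subdirectories under '", root, "'")
  images <- list(); labels <- character(0)
  for (cls in classes) {
    files <- sort(list.files(file.path(root, cls), full.names = TRUE,
                             pattern = "\\.(png|jpg|jpeg)$", ignore.case = TRUE))
    ok <- 0L
    for (f in files) {
      img <- tryCatch(read_one_image(f), error = function(e) {
        warning("skipping undecodable file '", f, "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cls)
      ok <- ok + 1L
    }
    if (ok == 0L) stop("class '", cls, "' has no decodable images")
  }
  leaf_image_set(images, labels, classes)
}

#' Per-channel mean and standard deviation of an image set
#'
#' @param set A `leaf_image_set`.
#' @return `list(mean =, sd =)`, each length 3.
#' @export
channel_stats <- function(set) {
  sums <- numeric(3); sqs <- numeric(3); n <- 0
  for (img in set$images) {
    for (c in 1:3) {
      sums[c] <- sums[c] + sum(img[, , c])
      sqs[c] <- sqs[c] + sum(img[, , c]^2)
    }
    n <- n + dim(img)[1] * dim(img)[2]
  }
  m <- sums / n
  list(mean = m, sd = sqrt(pmax(sqs / n - m^2, 1e-12)))
}

#' Standardize / de-standardize an image set with channel statistics
#'
#' @param set A `leaf_image_set`.
#' @param stats `list(mean=, sd=)` per channel.
#' @return The transformed set (with attribute `"stats"` when standardizing).
#' @export
standardize <- function(set, stats) {
  set$images <- lapply(set$images, function(img) {
    for (c in 1:3) img[, , c] <- (img[, , c] - stats$mean[c]) / stats$sd[c]
    img
  })
  attr(set, "stats") <- stats
  set
}

#' @rdname standardize
#' @export
destandardize <- function(set, stats) {
  set$images <- lapply(set$images, function(img) {
    for (c in 1:3) img[, , c] <- img[, , c] * stats$sd[c] + stats$mean[c]
    img
  })
  attr(set, "stats") <- NULL
  set
}
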