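#' Build a residual classifier from an architecture spec
#'
#' Constructs the trainable network described by a [arch_spec()]: a 7x7
#' stride-2 stem convolution with batch normalization and 3x3 max pooling,
#' four stages of basic blocks (two 3x3 convolutions with batch normalization
#' and rectifier each, a 1x1 projection shortcut where width or stride
#' changes), global average pooling and a linear head. If the spec enables
#' attention, the improved channel-attention module is attached after every
#' 3x3 convolution's batch-norm output and before its rectifier (stem
#' included; projection shortcuts excluded), with the 1D kernel size derived
#' from the channel count at that point.
#'
#' @param spec A valid [arch_spec()].
#' @param seed Optional integer seed for weight initialization; the caller's
#'   RNG state is left untouched.
#' @return An object of class `cacp_net`.
#' @examples
#' net <- build_model(arch_spec(num_classes = 5, input_size = 32,
#'                              stage_widths = c(8, 8, 8, 8),
#'                              stem_channels = 8), seed = 1)
#' count_parameters(net)
#' @export
build_model <- function(spec, seed = NULL) {
  validate_spec(spec)
  with_seed(seed, {
    att <- function(C) {
      if (!spec$attention_enabled) return(NULL)
      new_attention(C, kernel_size_from_channels(C, spec$attention_gamma,
                                                 spec$attention_b))
    }
    stem <- new.env(parent = emptyenv())
    stem$conv <- new_conv(3L, spec$stem_channels, 7L, 2L, 3L)
    stem$bn <- new_bn(spec$stem_channels)
    stem$att <- att(spec$stem_channels)

    stages <- vector("list", 4L)
    in_ch <- spec$stem_channels
    for (s in 1:4) {
      width <- spec$stage_widths[s]
      inner <- block_inner(spec, s)
      blocks <- vector("list", spec$blocks_per_stage[s])
      for (b in seq_len(spec$blocks_per_stage[s])) {
        stride <- if (b == 1L) spec$stage_strides[s] else 1L
        blk <- new.env(parent = emptyenv())
        blk$conv1 <- new_conv(in_ch, inner[b], 3L, stride, 1L)
        blk$bn1 <- new_bn(inner[b])
        blk$att1 <- att(inner[b])
        blk$conv2 <- new_conv(inner[b], width, 3L, 1L, 1L)
        blk$bn2 <- new_bn(width)
        blk$att2 <- att(width)
        if (stride != 1L || in_ch != width) {
          blk$down_conv <- new_conv(in_ch, width, 1L, stride, 0L)
          blk$down_bn <- new_bn(width)
        } else {
          blk$down_conv <- NULL
          blk$down_bn <- NULL
        }
        blocks[[b]] <- blk
        in_ch <- width
      }
      stages[[s]] <- blocks
    }
    head <- new_linear(spec$stage_widths[4], spec$num_classes)
    structure(list(spec = spec, stem = stem, stages = stages, head = head),
              class = "cacp_net")
  })
}

#' @export
print.cacp_net <- function(x, ...) {
  cat("<cacp_net> ")
  cat(sprintf("%s parameters, attention %s\n",
              format(count_parameters(x), big.mark = ","),
              if (x$spec$attention_enabled) "on" else "off"))
  print(x$spec)
  invisible(x)
}

# flat named list of every parameterized layer environment
net_layers <- function(net) {
  out <- list("stem.conv" = net$stem$conv, "stem.bn" = net$stem$bn)
  if (!is.null(net$stem$att)) out[["stem.att"]] <- net$stem$att
  for (s in 1:4) {
    for (b in seq_along(net$stages[[s]])) {
      blk <- net$stages[[s]][[b]]
      p <- sprintf("stage%d.block%d.", s, b)
      out[[paste0(p, "conv1")]] <- blk$conv1
      out[[paste0(p, "bn1")]] <- blk$bn1
      if (!is.null(blk$att1)) out[[paste0(p, "att1")]] <- blk$att1
      out[[paste0(p, "conv2")]] <- blk$conv2
      out[[paste0(p, "bn2")]] <- blk$bn2
      if (!is.null(blk$att2)) out[[paste0(p, "att2")]] <- blk$att2
      if (!is.null(blk$down_conv)) {
        out[[paste0(p, "down_conv")]] <- blk$down_conv
        out[[paste0(p, "down_bn")]] <- blk$down_bn
      }
    }
  }
  out[["head"]] <- net$head
  out
}

layer_param_count <- function(ly) {
  switch(ly$type,
         conv = length(ly$W),
         bn = length(ly$gamma) + length(ly$beta),
         attention = length(ly$w),
         linear = length(ly$W) + length(ly$b))
}

#' Count trainable parameters of a network
#'
#' Sums conv weights, batch-norm affine terms, attention kernels and the
#' linear head (weights and bias). Batch-norm running statistics are buffers,
#' not parameters; they are included only in serialized-size accounting.
#'
#' @param net A `cacp_net`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net_layers(net), layer_param_count, numeric(1)))
}

# persistent (non-trainable) buffer count: BN running mean + var
count_buffers <- function(net) {
  sum(vapply(net_layers(net), function(ly) {
    if (ly$type == "bn") length(ly$running_mean) + length(ly$running_var)
    else 0
  }, numeric(1)))
}

trace_conv <- function(trace, name, ly, fm_out) {
  if (is.null(trace)) return(invisible())
  trace$rows[[length(trace$rows) + 1L]] <-
    data.frame(layer = name, k = ly$k, c_in = ly$in_ch, c_out = ly$out_ch,
               h_out = fm_out$H, w_out = fm_out$W)
  invisible()
}

block_fwd <- function(blk, fm, training, cache, trace = NULL, name = "") {
  identity_in <- fm
  h1 <- conv_fwd(blk$conv1, fm, cache)
  trace_conv(trace, paste0(name, ".conv1"), blk$conv1, h1)
  if (!is.null(blk$capture_at) && blk$capture_at == "conv1") blk$captured <- h1
  h1 <- bn_fwd(blk$bn1, h1, training, cache)
  if (!is.null(blk$att1)) h1 <- att_fwd(blk$att1, h1, cache)
  if (cache) blk$mask1 <- h1$x > 0
  h1 <- relu_fwd(h1)
  h2 <- conv_fwd(blk$conv2, h1, cache)
  trace_conv(trace, paste0(name, ".conv2"), blk$conv2, h2)
  if (!is.null(blk$capture_at) && blk$capture_at == "conv2") blk$captured <- h2
  h2 <- bn_fwd(blk$bn2, h2, training, cache)
  if (!is.null(blk$att2)) h2 <- att_fwd(blk$att2, h2, cache)
  if (is.null(blk$down_conv)) {
    sc <- identity_in
  } else {
    sc <- conv_fwd(blk$down_conv, identity_in, cache)
    trace_conv(trace, paste0(name, ".down"), blk$down_conv, sc)
    sc <- bn_fwd(blk$down_bn, sc, training, cache)
  }
  y <- fmap(h2$x + sc$x, h2$H, h2$W, h2$N)
  if (cache) blk$mask2 <- y$x > 0
  relu_fwd(y)
}

block_bwd <- function(blk, dfm) {
  ds <- fmap(dfm$x * blk$mask2, dfm$H, dfm$W, dfm$N)
  blk$mask2 <- NULL
  # conv branch
  d2 <- ds
  if (!is.null(blk$att2)) d2 <- att_bwd(blk$att2, d2)
  d2 <- bn_bwd(blk$bn2, d2)
  if (!is.null(blk$capture_at) && blk$capture_at == "conv2") {
    blk$captured_grad <- d2
  }
  d1 <- conv_bwd(blk$conv2, d2)
  d1 <- fmap(d1$x * blk$mask1, d1$H, d1$W, d1$N)
  blk$mask1 <- NULL
  if (!is.null(blk$att1)) d1 <- att_bwd(blk$att1, d1)
  d1 <- bn_bwd(blk$bn1, d1)
  if (!is.null(blk$capture_at) && blk$capture_at == "conv1") {
    blk$captured_grad <- d1
  }
  din <- conv_bwd(blk$conv1, d1)
  # shortcut branch
  if (is.null(blk$down_conv)) {
    din$x <- din$x + ds$x
  } else {
    dsc <- bn_bwd(blk$down_bn, ds)
    dsc <- conv_bwd(blk$down_conv, dsc)
    din$x <- din$x + dsc$x
  }
  din
}

# forward pass over a batch; fm is a fmap of 3 x (H*W*N).
# trace: environment with $rows, filled with actual conv shapes (profiling
# oracle). cache: keep what backward needs.
net_forward <- function(net, fm, training = FALSE, cache = training,
                        trace = NULL) {
  stem <- net$stem
  h <- conv_fwd(stem$conv, fm, cache)
  trace_conv(trace, "stem.conv", stem$conv, h)
  if (!is.null(stem$capture_at) && stem$capture_at == "conv") stem$captured <- h
  h <- bn_fwd(stem$bn, h, training, cache)
  if (!is.null(stem$att)) h <- att_fwd(stem$att, h, cache)
  if (cache) stem$mask <- h$x > 0
  h <- relu_fwd(h)
  if (cache) stem$pre_pool <- c(h$H, h$W)
  h <- maxpool_fwd(stem, h, keep_cache = cache)
  for (s in 1:4) {
    for (b in seq_along(net$stages[[s]])) {
      h <- block_fwd(net$stages[[s]][[b]], h, training, cache, trace,
                     sprintf("stage%d.block%d", s, b))
    }
  }
  if (cache) net$head$gap_dims <- c(h$H, h$W, h$N)
  g <- gap_fwd(h)
  if (cache) net$head$cache <- list(g = g)
  z <- net$head$W %*% g + net$head$b
  if (!is.null(trace)) {
    trace$head <- data.frame(layer = "head", c_in = net$head$in_ch,
                             c_out = net$head$out_ch)
  }
  z
}

# backward from d(logits); populates layer gradients in place
net_backward <- function(net, dz) {
  head <- net$head
  head$gW <- dz %*% t(head$cache$g)
  head$gb <- rowSums(dz)
  dg <- crossprod(head$W, dz)
  head$cache <- NULL
  dims <- head$gap_dims
  dfm <- gap_bwd(dg, dims[1], dims[2], dims[3])
  for (s in 4:1) {
    for (b in rev(seq_along(net$stages[[s]]))) {
      dfm <- block_bwd(net$stages[[s]][[b]], dfm)
    }
  }
  stem <- net$stem
  dfm <- maxpool_bwd(stem, dfm, stem$pre_pool[1], stem$pre_pool[2])
  dfm <- fmap(dfm$x * stem$mask, dfm$H, dfm$W, dfm$N)
  stem$mask <- NULL; stem$pre_pool <- NULL
  if (!is.null(stem$att)) dfm <- att_bwd(stem$att, dfm)
  dfm <- bn_bwd(stem$bn, dfm)
  if (!is.null(stem$capture_at) && stem$capture_at == "conv") {
    stem$captured_grad <- dfm
  }
  conv_bwd(stem$conv, dfm)
}

# deep-copy all weights/buffers from one net into another with identical
# shapes (attention layers are copied only where both sides have them)
copy_weights <- function(from, to) {
  lf <- net_layers(from); lt <- net_layers(to)
  for (nm in names(lt)) {
    src <- lf[[nm]]
    dst <- lt[[nm]]
    if (is.null(src)) next
    if (dst$type == "conv") {
      dst$W <- src$W
    } else if (dst$type == "bn") {
      dst$gamma <- src$gamma; dst$beta <- src$beta
      dst$running_mean <- src$running_mean
      dst$running_var <- src$running_var
    } else if (dst$type == "attention") {
      if (dst$k == src$k) dst$w <- src$w
    } else if (dst$type == "linear") {
      dst$W <- src$W; dst$b <- src$b
    }
  }
  invisible(to)
}

#' Save / load a checkpoint with its architecture sidecar
#'
#' Weights and batch-norm buffers are written as an RDS file; the
#' architecture spec is written next to it as `<path>.json` so a pruned model
#' reloads without shape inference. `load_checkpoint()` refuses to load a
#' checkpoint whose sidecar is missing.
#'
#' @param net A `cacp_net`.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `save_checkpoint()`: the path, invisibly. `load_checkpoint()`: a
#'   `cacp_net`.
#' @export
save_checkpoint <- function(net, path) {
  state <- lapply(net_layers(net), function(ly) {
    switch(ly$type,
           conv = list(W = ly$W),
           bn = list(gamma = ly$gamma, beta = ly$beta,
                     running_mean = ly$running_mean,
                     running_var = ly$running_var),
           attention = list(w = ly$w),
           linear = list(W = ly$W, b = ly$b))
  })
  saveRDS(state, path)
  write_spec(net$spec, paste0(path, ".json"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("checkpoint sidecar '", sidecar, "' not found; every checkpoint ",
         "needs its architecture spec JSON next to it", call. = FALSE)
  }
  spec <- read_spec(sidecar)
  net <- build_model(spec, seed = 0L)
  state <- readRDS(path)
  layers <- net_layers(net)
  for (nm in names(layers)) {
    st <- state[[nm]]
    if (is.null(st)) stop("checkpoint missing layer '", nm, "'", call. = FALSE)
    for (f in names(st)) assign(f, st[[f]], envir = layers[[nm]])
  }
  net
}

#' Class probabilities / logits for a batch of images
#'
#' @param net A `cacp_net`.
#' @param x A list of images (H x W x 3 arrays in `[0,1]` or standardized
#'   floats) or a single such array.
#' @param type `"prob"` for softmax probabilities, `"logit"` for raw scores.
#' @param batch_size Mini-batch size used internally.
#' @return A matrix of `length(x)` rows and `num_classes` columns.
#' @export
predict_batch <- function(net, x, type = c("prob", "logit"),
                          batch_size = 32L) {
  type <- match.arg(type)
  if (is.array(x) && length(dim(x)) == 3L) x <- list(x)
  n <- length(x)
  out <- matrix(NA_real_, n, net$spec$num_classes)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fm <- images_to_fmap(x[idx])
    z <- net_forward(net, fm, training = FALSE, cache = FALSE)
    out[idx, ] <- t(z)
  }
  if (type == "prob") out <- softmax_rows(out)
  out
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# list of H x W x 3 numeric arrays -> fmap (3 x H*W*N, h fastest)
images_to_fmap <- function(imgs) {
  H <- dim(imgs[[1]])[1]; W <- dim(imgs[[1]])[2]
  x <- vapply(imgs, function(a) t(matrix(a, H * W, 3L)),
              matrix(0, 3, H * W))
  fmap(matrix(x, 3L, H * W * length(imgs)), H, W, length(imgs))
}
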