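# Internal layer primitives.
#
# Activations travel as "fmap" lists: list(x = C x (H*W*N) matrix, H, W, N)
# with column order h-fastest, then w, then sample. Layers are environments
# holding parameters, momentum buffers, gradients and forward caches, so SGD
# updates happen in place.

fmap <- function(x, H, W, N) list(x = x, H = H, W = W, N = N)

# evaluate expr under a temporary RNG state seeded with `seed` (NULL = use
# the current RNG stream)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

new_conv <- function(in_ch, out_ch, k, stride, pad) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv"
  e$in_ch <- in_ch; e$out_ch <- out_ch
  e$k <- k; e$stride <- stride; e$pad <- pad
  sd <- sqrt(2 / (in_ch * k * k))
  e$W <- matrix(stats::rnorm(out_ch * in_ch * k * k, 0, sd),
                out_ch, in_ch * k * k)
  e$vW <- matrix(0, out_ch, in_ch * k * k)
  e
}

# index of input columns sampled by a 1x1 strided conv (pad must be 0)
strided_cols <- function(H, W, N, stride) {
  Ho <- (H - 1L) %/% stride + 1L
  Wo <- (W - 1L) %/% stride + 1L
  h <- seq.int(1L, by = stride, length.out = Ho)
  w <- seq.int(1L, by = stride, length.out = Wo)
  base <- as.vector(outer(h, (w - 1L) * H, `+`))          # h fastest
  idx <- as.vector(outer(base, (seq_len(N) - 1L) * H * W, `+`))
  list(idx = idx, H = Ho, W = Wo)
}

conv_fwd <- function(ly, fm, keep_cache = FALSE) {
  if (ly$k == 1L && ly$pad == 0L) {
    sc <- strided_cols(fm$H, fm$W, fm$N, ly$stride)
    cols <- fm$x[, sc$idx, drop = FALSE]
    Ho <- sc$H; Wo <- sc$W
  } else {
    cols <- cpp_im2col(fm$x, ly$in_ch, fm$H, fm$W, fm$N,
                       ly$k, ly$stride, ly$pad)
    Ho <- (fm$H + 2L * ly$pad - ly$k) %/% ly$stride + 1L
    Wo <- (fm$W + 2L * ly$pad - ly$k) %/% ly$stride + 1L
  }
  y <- ly$W %*% cols
  if (keep_cache) {
    ly$cache <- list(cols = cols, H = fm$H, W = fm$W, N = fm$N)
  }
  fmap(y, Ho, Wo, fm$N)
}

conv_bwd <- function(ly, dfm) {
  cc <- ly$cache
  dy <- dfm$x
  ly$gW <- dy %*% t(cc$cols)
  dcols <- crossprod(ly$W, dy)
  if (ly$k == 1L && ly$pad == 0L) {
    dx <- matrix(0, ly$in_ch, cc$H * cc$W * cc$N)
    sc <- strided_cols(cc$H, cc$W, cc$N, ly$stride)
    dx[, sc$idx] <- dcols
  } else {
    dx <- cpp_col2im(dcols, ly$in_ch, cc$H, cc$W, cc$N,
                     ly$k, ly$stride, ly$pad)
  }
  ly$cache <- NULL
  fmap(dx, cc$H, cc$W, cc$N)
}

new_bn <- function(C) {
  e <- new.env(parent = emptyenv())
  e$type <- "bn"
  e$C <- C
  e$gamma <- rep(1, C); e$beta <- rep(0, C)
  e$vgamma <- rep(0, C); e$vbeta <- rep(0, C)
  e$running_mean <- rep(0, C); e$running_var <- rep(1, C)
  e$momentum <- 0.1; e$eps <- 1e-5
  e
}

bn_fwd <- function(ly, fm, training = FALSE, keep_cache = FALSE) {
  x <- fm$x
  if (training) {
    m <- rowMeans(x)
    v <- rowMeans((x - m)^2)
    ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * m
    ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * v
  } else {
    m <- ly$running_mean
    v <- ly$running_var
  }
  invstd <- 1 / sqrt(v + ly$eps)
  xhat <- (x - m) * invstd
  y <- xhat * ly$gamma + ly$beta
  if (keep_cache) ly$cache <- list(xhat = xhat, invstd = invstd,
                                   training = training)
  fmap(y, fm$H, fm$W, fm$N)
}

bn_bwd <- function(ly, dfm) {
  cc <- ly$cache
  dy <- dfm$x
  xhat <- cc$xhat
  ly$ggamma <- rowSums(dy * xhat)
  ly$gbeta <- rowSums(dy)
  dxhat <- dy * ly$gamma
  if (cc$training) {
    dx <- cc$invstd *
      (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  } else {
    dx <- dxhat * cc$invstd
  }
  ly$cache <- NULL
  fmap(dx, dfm$H, dfm$W, dfm$N)
}

new_attention <- function(C, k) {
  stopifnot(k %% 2L == 1L, k >= 1L)
  e <- new.env(parent = emptyenv())
  e$type <- "attention"
  e$C <- C; e$k <- k
  e$w <- (stats::runif(k) * 2 - 1) / sqrt(k)
  e$vw <- rep(0, k)
  e
}

# zero-padded 1D convolution across the channel axis, one shared kernel;
# g and the result are C x N
conv1d_channels <- function(g, w) {
  k <- length(w)
  half <- (k - 1L) %/% 2L
  C <- nrow(g)
  out <- matrix(0, C, ncol(g))
  for (j in seq_len(k)) {
    o <- j - half - 1L                # source offset relative to destination
    dst <- seq_len(C)
    src <- dst + o
    ok <- src >= 1L & src <= C
    if (any(ok)) {
      out[dst[ok], ] <- out[dst[ok], , drop = FALSE] +
        w[j] * g[src[ok], , drop = FALSE]
    }
  }
  out
}

att_fwd <- function(ly, fm, keep_cache = FALSE) {
  HW <- fm$H * fm$W
  pool <- cpp_avgmax_pool(fm$x, ly$C, HW, fm$N)
  g <- pool$avg + pool$max
  pre <- conv1d_channels(g, ly$w)
  omega <- 1 / (1 + exp(-pre))
  y <- cpp_scale_channels(fm$x, omega, HW)
  if (keep_cache) {
    ly$cache <- list(x = fm$x, g = g, omega = omega, argmax = pool$argmax,
                     HW = HW, N = fm$N)
  }
  fmap(y, fm$H, fm$W, fm$N)
}

att_bwd <- function(ly, dfm) {
  cc <- ly$cache
  dy <- dfm$x
  HW <- cc$HW; N <- cc$N; C <- ly$C
  dx <- cpp_scale_channels(dy, cc$omega, HW)
  domega <- cpp_channel_dot(dy, cc$x, HW, N)
  dpre <- domega * cc$omega * (1 - cc$omega)
  # kernel gradient and transposed convolution back to the descriptor
  k <- ly$k
  half <- (k - 1L) %/% 2L
  gw <- numeric(k)
  dg <- matrix(0, C, N)
  for (j in seq_len(k)) {
    o <- j - half - 1L
    dst <- seq_len(C)
    src <- dst + o
    ok <- src >= 1L & src <= C
    if (any(ok)) {
      gw[j] <- sum(dpre[dst[ok], , drop = FALSE] * cc$g[src[ok], , drop = FALSE])
      dg[src[ok], ] <- dg[src[ok], , drop = FALSE] +
        ly$w[j] * dpre[dst[ok], , drop = FALSE]
    }
  }
  ly$gw <- gw
  # descriptor = average + max pooling: spread dg/HW everywhere, add dg at argmax
  dx_pool <- dg[, rep(seq_len(N), each = HW), drop = FALSE] / HW
  col_at <- as.vector(cc$argmax) + 1L + rep((seq_len(N) - 1L) * HW, each = C)
  at <- cbind(rep(seq_len(C), N), col_at)
  dx_pool[at] <- dx_pool[at] + as.vector(dg)
  ly$cache <- NULL
  fmap(dx + dx_pool, dfm$H, dfm$W, dfm$N)
}

new_linear <- function(in_ch, out_ch) {
  e <- new.env(parent = emptyenv())
  e$type <- "linear"
  e$in_ch <- in_ch; e$out_ch <- out_ch
  sd <- sqrt(2 / in_ch)
  e$W <- matrix(stats::rnorm(out_ch * in_ch, 0, sd), out_ch, in_ch)
  e$b <- rep(0, out_ch)
  e$vW <- matrix(0, out_ch, in_ch)
  e$vb <- rep(0, out_ch)
  e
}

relu_fwd <- function(fm) {
  fmap(pmax(fm$x, 0), fm$H, fm$W, fm$N)
}

maxpool_fwd <- function(env, fm, k = 3L, stride = 2L, pad = 1L,
                        keep_cache = FALSE) {
  r <- cpp_maxpool_fwd(fm$x, nrow(fm$x), fm$H, fm$W, fm$N, k, stride, pad)
  if (keep_cache) {
    env$pool_cache <- list(idx = r$idx, in_cols = ncol(fm$x))
  }
  fmap(r$out, r$H, r$W, fm$N)
}

maxpool_bwd <- function(env, dfm, H, W) {
  cc <- env$pool_cache
  dx <- cpp_maxpool_bwd(dfm$x, cc$idx, nrow(dfm$x), cc$in_cols)
  env$pool_cache <- NULL
  fmap(dx, H, W, dfm$N)
}

# global average pooling: fm -> C x N feature matrix
gap_fwd <- function(fm) {
  HW <- fm$H * fm$W
  g <- matrix(0, nrow(fm$x), fm$N)
  for (n in seq_len(fm$N)) {
    g[, n] <- rowMeans(fm$x[, (n - 1L) * HW + seq_len(HW), drop = FALSE])
  }
  g
}

gap_bwd <- function(dg, H, W, N) {
  HW <- H * W
  fmap(dg[, rep(seq_len(N), each = HW), drop = FALSE] / HW, H, W, N)
}

# one SGD-with-momentum step for every parameter of a layer; weight decay is
# applied to conv and linear weight matrices only
layer_step <- function(ly, lr, momentum, weight_decay) {
  if (ly$type == "conv") {
    if (is.null(ly$gW)) return(invisible())
    ly$vW <- momentum * ly$vW + ly$gW + weight_decay * ly$W
    ly$W <- ly$W - lr * ly$vW
    ly$gW <- NULL
  } else if (ly$type == "bn") {
    if (is.null(ly$ggamma)) return(invisible())
    ly$vgamma <- momentum * ly$vgamma + ly$ggamma
    ly$vbeta <- momentum * ly$vbeta + ly$gbeta
    ly$gamma <- ly$gamma - lr * ly$vgamma
    ly$beta <- ly$beta - lr * ly$vbeta
    ly$ggamma <- NULL; ly$gbeta <- NULL
  } else if (ly$type == "attention") {
    if (is.null(ly$gw)) return(invisible())
    ly$vw <- momentum * ly$vw + ly$gw
    ly$w <- ly$w - lr * ly$vw
    ly$gw <- NULL
  } else if (ly$type == "linear") {
    if (is.null(ly$gW)) return(invisible())
    ly$vW <- momentum * ly$vW + ly$gW + weight_decay * ly$W
    ly$vb <- momentum * ly$vb + ly$gb
    ly$W <- ly$W - lr * ly$vW
    ly$b <- ly$b - lr * ly$vb
    ly$gW <- NULL; ly$gb <- NULL
  }
  invisible()
}
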