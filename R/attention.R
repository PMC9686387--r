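#' Adaptive 1D kernel size from channel count
#'
#' The cross-channel interaction range k of the attention module grows with
#' the channel count C through the mapping
#' `t = floor((log2(C) + b) / gamma)`, rounded up to the next odd integer and
#' clamped to `[1, C]` (next lower odd when C is exceeded). With the defaults
#' `gamma = 2`, `b = 1` this gives k = 3 at C = 64 and k = 5 at C = 512.
#'
#' @param C Channel count (positive integer).
#' @param gamma,b Mapping parameters.
#' @return An odd positive integer kernel size.
#' @examples
#' kernel_size_from_channels(64)   # 3
#' kernel_size_from_channels(512)  # 5
#' @export
kernel_size_from_channels <- function(C, gamma = 2, b = 1) {
  if (length(C) != 1L || is.na(C) || C < 1) {
    stop("C must be a positive integer", call. = FALSE)
  }
  C <- as.integer(C)
  t <- floor((log2(C) + b) / gamma)
  k <- if (t %% 2 == 1) t else t + 1
  k <- max(k, 1L)
  if (k > C) k <- if (C %% 2 == 1) C else C - 1L
  as.integer(max(k, 1L))
}

#' Combined global average + max channel descriptor
#'
#' Reduces a C x H x W feature map to one scalar per channel: the spatial mean
#' plus the spatial maximum. Max pooling preserves small, localized lesion
#' responses that average pooling dilutes; the sum keeps both the global and
#' the peak signal.
#'
#' @param x Numeric array of shape C x H x W.
#' @return Numeric vector of length C.
#' @examples
#' x <- array(2, c(3, 4, 4))
#' global_descriptor(x)  # mean 2 + max 2 = 4 per channel
#' @export
global_descriptor <- function(x) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a C x H x W array", call. = FALSE)
  if (d[2] < 1L || d[3] < 1L) {
    stop("feature map has empty spatial extent", call. = FALSE)
  }
  m <- apply(x, 1, mean)
  mx <- apply(x, 1, max)
  m + mx
}

#' Band kernel for local cross-channel interaction
#'
#' A length-k weight vector realizing a band matrix acting on the channel
#' descriptor: each channel's attention logit is a k-wide window over
#' neighbouring channels' descriptors, shared across channels, zero-padded at
#' the ends so the output length equals C. No bias term.
#'
#' @param weights Numeric vector of odd length.
#' @return An object of class `band_kernel`.
#' @export
band_kernel <- function(weights) {
  k <- length(weights)
  if (k %% 2L != 1L) {
    stop("band kernel size must be odd, got ", k, call. = FALSE)
  }
  structure(list(k = as.integer(k), weights = as.numeric(weights),
                 padding = (k - 1L) %/% 2L),
            class = "band_kernel")
}

#' Channel-attention weights from a descriptor
#'
#' Convolves the length-C global descriptor with the shared 1D band kernel
#' (zero padding, same-length output) and squashes with the logistic sigmoid,
#' yielding one gate in (0,1) per channel.
#'
#' @param g Numeric vector (length C) or C x N matrix of descriptors.
#' @param kern A [band_kernel()].
#' @return Attention weights with the same shape as `g`, each in (0,1).
#' @export
attention_weights <- function(g, kern) {
  if (!inherits(kern, "band_kernel")) kern <- band_kernel(kern)
  vec <- is.null(dim(g))
  gm <- if (vec) matrix(g, ncol = 1L) else g
  if (kern$k > nrow(gm)) {
    stop("kernel size ", kern$k, " exceeds channel count ", nrow(gm),
         call. = FALSE)
  }
  pre <- conv1d_channels(gm, kern$weights)
  omega <- 1 / (1 + exp(-pre))
  if (vec) drop(omega) else omega
}

#' Gate a feature map by per-channel attention weights
#'
#' @param x Numeric array C x H x W.
#' @param w Numeric vector of length C with entries in `[0, 1]`.
#' @return The gated array, same shape as `x`.
#' @export
apply_attention <- function(x, w) {
  d <- dim(x)
  if (length(d) != 3L) stop("x must be a C x H x W array", call. = FALSE)
  if (length(w) != d[1]) {
    stop("attention weight length ", length(w),
         " does not match channel count ", d[1], call. = FALSE)
  }
  x * as.vector(w)   # w recycles over the fastest (channel) dimension
}

#' Attach the channel-attention module to a plain network
#'
#' Returns a new network with one attention module after every 3x3
#' convolution's batch normalization and before its rectifier (the 7x7 stem
#' included; 1x1 projection shortcuts excluded). All existing conv/BN/head
#' weights are copied; attention kernels are freshly initialized (symmetric
#' uniform scaled by 1/sqrt(k), seeded). For the default 18-layer spec this
#' adds 17 modules and a parameter overhead of exactly the sum of their
#' kernel sizes.
#'
#' @param net A `cacp_net` built without attention.
#' @param spec The spec to use (defaults to the network's own, with attention
#'   switched on).
#' @param seed Seed for attention-kernel initialization.
#' @return A new `cacp_net` with attention enabled.
#' @export
attach_attention <- function(net, spec = NULL, seed = NULL) {
  spec <- spec %||% net$spec
  spec$attention_enabled <- TRUE
  out <- build_model(spec, seed = seed)
  copy_weights(net, out)
  out
}

#' Attention modules and their kernel sizes for a spec
#'
#' @param spec A `cacp_spec`.
#' @return A data.frame with one row per attention module (location, channel
#'   count, kernel size). The parameter overhead of attaching attention is
#'   `sum($k)`.
#' @export
attention_modules <- function(spec) {
  validate_spec(spec)
  rows <- list(data.frame(layer = "stem.conv", channels = spec$stem_channels))
  for (s in 1:4) {
    inner <- block_inner(spec, s)
    for (b in seq_len(spec$blocks_per_stage[s])) {
      rows[[length(rows) + 1L]] <- data.frame(
        layer = sprintf("stage%d.block%d.conv1", s, b), channels = inner[b])
      rows[[length(rows) + 1L]] <- data.frame(
        layer = sprintf("stage%d.block%d.conv2", s, b),
        channels = spec$stage_widths[s])
    }
  }
  out <- do.call(rbind, rows)
  out$k <- vapply(out$channels, kernel_size_from_channels, integer(1),
                  gamma = spec$attention_gamma, b = spec$attention_b)
  out
}
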