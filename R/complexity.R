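#' FLOPs of one convolution layer
#'
#' Under the `"paper"` convention a multiply-add counts as two floating-point
#' operations: `2 * k^2 * C_in * h_out * w_out * C_out`. Under the `"mac"`
#' convention (the one standard profiling tools report for this architecture
#' family, and the default for table reproduction) a multiply-accumulate
#' counts once, i.e. half that.
#'
#' @param k Square kernel size.
#' @param c_in,c_out Input / output channel counts.
#' @param h_out,w_out Output spatial extents.
#' @param convention `"paper"` or `"mac"`.
#' @return Operation count.
#' @examples
#' conv_flops(3, 2, 4, 8, 8, "paper")  # 9216
#' conv_flops(3, 2, 4, 8, 8, "mac")    # 4608
#' @export
conv_flops <- function(k, c_in, c_out, h_out, w_out,
                       convention = c("mac", "paper")) {
  convention <- match.arg(convention)
  args <- c(k = k, c_in = c_in, c_out = c_out, h_out = h_out, w_out = w_out)
  if (any(args < 1)) {
    stop("nonpositive argument: ",
         paste(names(args)[args < 1], collapse = ", "), call. = FALSE)
  }
  macs <- k^2 * c_in * h_out * w_out * c_out
  if (convention == "paper") 2 * macs else macs
}

#' Parameter count of one convolution layer
#'
#' `C_out * (C_in * k^2 + 1)` with a bias term, `C_out * C_in * k^2` without.
#' The backbone's convolutions are bias-free (batch normalization follows
#' each), so profiling uses `with_bias = FALSE` for them.
#'
#' @param k Square kernel size.
#' @param c_in,c_out Input / output channel counts.
#' @param with_bias Include one bias per output channel?
#' @return Parameter count.
#' @examples
#' conv_params(3, 2, 4, with_bias = TRUE)   # 76
#' conv_params(3, 64, 64, with_bias = FALSE) # 36864
#' @export
conv_params <- function(k, c_in, c_out, with_bias = TRUE) {
  args <- c(k = k, c_in = c_in, c_out = c_out)
  if (any(args < 1)) {
    stop("nonpositive argument: ",
         paste(names(args)[args < 1], collapse = ", "), call. = FALSE)
  }
  if (with_bias) c_out * (c_in * k^2 + 1) else c_out * c_in * k^2
}

# spatial sizes and layer layout of an architecture at a given input size;
# one row per accounted layer
arch_layout <- function(spec, input_size) {
  out_sz <- function(s, k, stride, pad) (s + 2L * pad - k) %/% stride + 1L
  rows <- list()
  add <- function(layer, type, k, c_in, c_out, h, w) {
    rows[[length(rows) + 1L]] <<-
      data.frame(layer = layer, type = type, k = k, c_in = c_in,
                 c_out = c_out, h_out = h, w_out = w)
  }
  s0 <- out_sz(input_size, 7L, 2L, 3L)
  add("stem.conv", "conv", 7L, 3L, spec$stem_channels, s0, s0)
  add("stem.bn", "bn", 0L, spec$stem_channels, spec$stem_channels, s0, s0)
  if (spec$attention_enabled) {
    add("stem.att", "attention",
        kernel_size_from_channels(spec$stem_channels, spec$attention_gamma,
                                  spec$attention_b),
        spec$stem_channels, spec$stem_channels, 1L, 1L)
  }
  add("stem.relu", "relu", 0L, spec$stem_channels, spec$stem_channels, s0, s0)
  sp <- out_sz(s0, 3L, 2L, 1L)
  add("stem.pool", "pool", 3L, spec$stem_channels, spec$stem_channels, sp, sp)
  sz <- sp
  in_ch <- spec$stem_channels
  for (s in 1:4) {
    width <- spec$stage_widths[s]
    inner <- block_inner(spec, s)
    for (b in seq_len(spec$blocks_per_stage[s])) {
      stride <- if (b == 1L) spec$stage_strides[s] else 1L
      osz <- out_sz(sz, 3L, stride, 1L)
      p <- sprintf("stage%d.block%d.", s, b)
      add(paste0(p, "conv1"), "conv", 3L, in_ch, inner[b], osz, osz)
      add(paste0(p, "bn1"), "bn", 0L, inner[b], inner[b], osz, osz)
      if (spec$attention_enabled) {
        add(paste0(p, "att1"), "attention",
            kernel_size_from_channels(inner[b], spec$attention_gamma,
                                      spec$attention_b),
            inner[b], inner[b], 1L, 1L)
      }
      add(paste0(p, "relu1"), "relu", 0L, inner[b], inner[b], osz, osz)
      add(paste0(p, "conv2"), "conv", 3L, inner[b], width, osz, osz)
      add(paste0(p, "bn2"), "bn", 0L, width, width, osz, osz)
      if (spec$attention_enabled) {
        add(paste0(p, "att2"), "attention",
            kernel_size_from_channels(width, spec$attention_gamma,
                                      spec$attention_b),
            width, width, 1L, 1L)
      }
      if (stride != 1L || in_ch != width) {
        add(paste0(p, "down.conv"), "conv", 1L, in_ch, width, osz, osz)
        add(paste0(p, "down.bn"), "bn", 0L, width, width, osz, osz)
      }
      add(paste0(p, "relu2"), "relu", 0L, width, width, osz, osz)
      sz <- osz
      in_ch <- width
    }
  }
  add("gap", "pool", sz, spec$stage_widths[4], spec$stage_widths[4], 1L, 1L)
  add("head", "linear", 1L, spec$stage_widths[4], spec$num_classes, 1L, 1L)
  do.call(rbind, rows)
}

#' Profile FLOPs, parameters and serialized size
#'
#' Closed-form accounting over the architecture: convolution FLOPs/parameters
#' per [conv_flops()] / [conv_params()] (bias-free), batch-norm affine
#' parameters, attention 1D kernels (parameters exactly the kernel sizes,
#' MACs `k * C` per module), and the linear head (`C_in * C_out` MACs plus
#' bias). Serialized size assumes 32-bit floats:
#' `4 * (parameters + persistent buffers) / 2^20` mebibytes, the buffers being
#' batch-norm running statistics.
#'
#' Elementwise operations (batch-norm normalization, rectifiers, pooling) are
#' excluded from FLOPs by default; `include_elementwise = TRUE` adds one
#' operation per output element for them, which accounts for the residual
#' between common profiling tools.
#'
#' @param x A `cacp_spec` or `cacp_net`.
#' @param input_size Input resolution (defaults to the spec's).
#' @param convention `"mac"` (default) or `"paper"` (multiply-adds counted
#'   twice).
#' @param include_elementwise Count elementwise ops in FLOPs?
#' @return A `cacp_complexity` object: totals (`flops`, `params`, `buffers`,
#'   `size_mib`, `gflops`, `mparams`) and a per-layer `breakdown` data.frame.
#' @examples
#' rep <- profile_model(spec_peanut())
#' rep
#' @export
profile_model <- function(x, input_size = NULL,
                          convention = c("mac", "paper"),
                          include_elementwise = FALSE) {
  UseMethod("profile_model")
}

#' @export
profile_model.cacp_net <- function(x, input_size = NULL,
                                   convention = c("mac", "paper"),
                                   include_elementwise = FALSE) {
  profile_model(x$spec, input_size = input_size, convention = convention,
                include_elementwise = include_elementwise)
}

#' @export
profile_model.cacp_spec <- function(x, input_size = NULL,
                                    convention = c("mac", "paper"),
                                    include_elementwise = FALSE) {
  convention <- match.arg(convention)
  spec <- validate_spec(x)
  input_size <- as.integer(input_size %||% spec$input_size)
  if (input_size < 32L) stop("input_size must be >= 32", call. = FALSE)
  lay <- arch_layout(spec, input_size)
  mult <- if (convention == "paper") 2 else 1
  n <- nrow(lay)
  params <- flops <- buffers <- numeric(n)
  for (i in seq_len(n)) {
    r <- lay[i, ]
    if (r$type == "conv") {
      params[i] <- conv_params(r$k, r$c_in, r$c_out, with_bias = FALSE)
      flops[i] <- conv_flops(r$k, r$c_in, r$c_out, r$h_out, r$w_out,
                             convention)
    } else if (r$type == "bn") {
      params[i] <- 2 * r$c_out
      buffers[i] <- 2 * r$c_out
      if (include_elementwise) flops[i] <- r$c_out * r$h_out * r$w_out
    } else if (r$type == "attention") {
      params[i] <- r$k
      flops[i] <- mult * r$k * r$c_out
    } else if (r$type == "linear") {
      params[i] <- r$c_in * r$c_out + r$c_out
      flops[i] <- mult * (r$c_in * r$c_out + r$c_out)
    } else if (r$type %in% c("relu", "pool")) {
      if (include_elementwise) flops[i] <- r$c_out * r$h_out * r$w_out
    }
  }
  lay$params <- params
  lay$flops <- flops
  lay$buffers <- buffers
  total_params <- sum(params)
  total_buffers <- sum(buffers)
  structure(list(
    flops = sum(flops),
    params = total_params,
    buffers = total_buffers,
    size_mib = 4 * (total_params + total_buffers) / 2^20,
    gflops = sum(flops) / 1e9,
    mparams = total_params / 1e6,
    convention = convention,
    include_elementwise = include_elementwise,
    input_size = input_size,
    breakdown = lay
  ), class = "cacp_complexity")
}

#' @export
print.cacp_complexity <- function(x, ...) {
  cat(sprintf("<cacp_complexity> %.3f GFLOPs (%s) | %.3f M params | %.1f MiB | input %d\n",
              x$gflops, x$convention, x$mparams, x$size_mib, x$input_size))
  invisible(x)
}

#' @export
as.data.frame.cacp_complexity <- function(x, ...) x$breakdown

#' Measure complexity from an actual forward pass
#'
#' Runs one forward pass of the network on a zero image, records every
#' convolution's realized input/output shapes, and recomputes FLOPs and
#' parameters from those shapes together with the actual parameter arrays.
#' This is the measurement-based counterpart of the closed-form
#' [profile_model()]; the two agree to well under 0.1 percent.
#'
#' @param net A `cacp_net`.
#' @param input_size Input resolution.
#' @param convention `"mac"` or `"paper"`.
#' @return A list with `flops`, `params`, `buffers`, `size_mib` and the traced
#'   per-conv shape table.
#' @export
profile_from_forward <- function(net, input_size = NULL,
                                 convention = c("mac", "paper")) {
  convention <- match.arg(convention)
  input_size <- as.integer(input_size %||% net$spec$input_size)
  mult <- if (convention == "paper") 2 else 1
  trace <- new.env()
  trace$rows <- list()
  fm <- fmap(matrix(0, 3, input_size^2), input_size, input_size, 1L)
  invisible(net_forward(net, fm, training = FALSE, cache = FALSE,
                        trace = trace))
  shapes <- do.call(rbind, trace$rows)
  flops <- sum(mapply(conv_flops, shapes$k, shapes$c_in, shapes$c_out,
                      shapes$h_out, shapes$w_out,
                      MoreArgs = list(convention = convention)))
  layers <- net_layers(net)
  params <- sum(vapply(layers, layer_param_count, numeric(1)))
  for (ly in layers) {
    if (ly$type == "attention") flops <- flops + mult * ly$k * ly$C
    if (ly$type == "linear") {
      flops <- flops + mult * (length(ly$W) + length(ly$b))
    }
  }
  buffers <- count_buffers(net)
  list(flops = flops, params = params, buffers = buffers,
       size_mib = 4 * (params + buffers) / 2^20, shapes = shapes)
}

#' Percentage reductions between two complexity reports
#'
#' @param before,after `cacp_complexity` objects.
#' @return A data.frame with the before/after totals and
#'   `100 * (1 - after/before)` percentages for FLOPs, parameters and size.
#' @export
complexity_reduction <- function(before, after) {
  data.frame(
    metric = c("gflops", "mparams", "size_mib"),
    before = c(before$gflops, before$mparams, before$size_mib),
    after = c(after$gflops, after$mparams, after$size_mib),
    reduction_pct = 100 * (1 - c(after$gflops / before$gflops,
                                 after$mparams / before$mparams,
                                 after$size_mib / before$size_mib))
  )
}

#' Published reference complexity of the original models
#'
#' Complexity totals reported for the original ResNet-18 baseline and the
#' attention-pruned CACPNET model (GFLOPs, millions of parameters, serialized
#' size in MiB). Emitted alongside achieved totals so pruned-profile runs
#' always show both; the published pruned totals are not reproduced by the
#' literal per-block reading of the compression-ratio schedule (see the
#' methods vignette), so the two may differ.
#'
#' @return A data.frame with rows `baseline` and `cacpnet`.
#' @export
reference_complexity <- function() {
  data.frame(
    model = c("baseline", "cacpnet"),
    gflops = c(1.819, 1.267),
    mparams = c(11.180, 4.699),
    size_mib = c(42.7, 18.0)
  )
}

#' Write a complexity report as JSON and per-layer CSV
#'
#' @param report A `cacp_complexity`.
#' @param path_json,path_csv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
write_complexity <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(gflops = report$gflops, mparams = report$mparams,
           size_mib = report$size_mib, flops = report$flops,
           params = report$params, buffers = report$buffers,
           convention = report$convention,
           input_size = report$input_size),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    utils::write.csv(report$breakdown, path_csv, row.names = FALSE)
  }
  invisible(report)
}
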