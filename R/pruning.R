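#' Norm-based importance of a convolution's output channels
#'
#' Reduces each output channel's weight slice (C_in x k x k values) to a
#' single nonnegative score: the sum of absolute values (`"l1"`, the default
#' ranking used throughout the pruning procedure) or the square root of the
#' sum of squares (`"l2"`).
#'
#' @param weights A conv weight: a 4D array `C_out x C_in x k x k`, a matrix
#'   `C_out x (C_in*k^2)`, or a conv layer taken from a network.
#' @param norm_kind `"l1"` or `"l2"`.
#' @return Numeric vector of length `C_out` with attribute `norm_kind`.
#' @examples
#' w <- array(c(1, -2), c(1, 2, 1, 1))
#' channel_importance(w, "l1")  # 3
#' channel_importance(w, "l2")  # sqrt(5)
#' @export
channel_importance <- function(weights, norm_kind = c("l1", "l2")) {
  norm_kind <- match.arg(norm_kind)
  if (is.environment(weights) && identical(weights$type, "conv")) {
    weights <- weights$W
  }
  if (is.array(weights) && length(dim(weights)) == 4L) {
    d <- dim(weights)
    weights <- matrix(aperm(weights, c(2, 3, 4, 1)), d[2] * d[3] * d[4], d[1])
    weights <- t(weights)
  }
  if (!is.matrix(weights)) {
    stop("weights must be a 4D array or C_out x (C_in*k^2) matrix",
         call. = FALSE)
  }
  scores <- if (norm_kind == "l1") {
    rowSums(abs(weights))
  } else {
    sqrt(rowSums(weights^2))
  }
  attr(scores, "norm_kind") <- norm_kind
  scores
}

#' Number of channels removed at a compression ratio
#'
#' `P = floor(R * n_out)`, additionally capped at `n_out - 1` so at least one
#' channel always survives.
#'
#' @param R Local compression ratio in `[0, 1)`.
#' @param n_out Output channel count of the layer.
#' @return Nonnegative integer count of channels to remove.
#' @examples
#' prune_count(0.3, 512)  # 153
#' prune_count(0.1, 128)  # 12
#' @export
prune_count <- function(R, n_out) {
  if (length(R) != 1L || is.na(R) || R < 0 || R >= 1) {
    stop("compression ratio R must lie in [0, 1)", call. = FALSE)
  }
  if (n_out < 1) stop("n_out must be >= 1", call. = FALSE)
  min(floor(R * n_out), n_out - 1L)
}

#' Channels removed from a residual shortcut
#'
#' The shortcut path of a basic block must end with the same channels as the
#' block's second convolution; the number removed from it is the difference
#' between the original shortcut width and the pruned conv width.
#'
#' @param o_r Original shortcut output channel count.
#' @param o_conv2 Output channel count of the pruned second convolution.
#' @return `o_r - o_conv2`.
#' @examples
#' residual_prune_count(512, 359)  # 153
#' @export
residual_prune_count <- function(o_r, o_conv2) {
  if (o_conv2 < 1) stop("o_conv2 must be >= 1", call. = FALSE)
  if (o_conv2 > o_r) {
    stop("pruned conv width (", o_conv2,
         ") exceeds shortcut width (", o_r, ")", call. = FALSE)
  }
  o_r - o_conv2
}

#' Validate a local compression-ratio schedule
#'
#' One ratio per basic block, shallow to deep. The published schedule for the
#' 8-block backbone is `c(0, 0, 0.1, 0.1, 0.2, 0.2, 0.3, 0.3)`.
#'
#' @param R Numeric vector of ratios, each in `[0, 1)`.
#' @param spec The spec the schedule applies to.
#' @return `R`, invisibly.
#' @export
validate_schedule <- function(R, spec) {
  n_blocks <- sum(spec$blocks_per_stage)
  if (length(R) != n_blocks) {
    stop("schedule length ", length(R), " does not match the spec's ",
         n_blocks, " basic blocks", call. = FALSE)
  }
  if (any(is.na(R)) || any(R < 0) || any(R >= 1)) {
    stop("all schedule entries must lie in [0, 1)", call. = FALSE)
  }
  invisible(R)
}

#' Default local compression-ratio schedule
#'
#' @return `c(0, 0, 0.1, 0.1, 0.2, 0.2, 0.3, 0.3)` — one ratio per basic
#'   block, shallow to deep; shallow layers are pruned less because they are
#'   more sensitive.
#' @export
default_schedule <- function() c(0, 0, 0.1, 0.1, 0.2, 0.2, 0.3, 0.3)

# top-n surviving indices by importance, ties broken toward lower index;
# returned sorted increasing
top_surviving <- function(scores, n_keep) {
  ord <- order(-scores, seq_along(scores))
  sort(ord[seq_len(n_keep)])
}

#' Build a structured channel-pruning plan
#'
#' Ranks output channels by norm-based importance and selects survivors per
#' the compression-ratio schedule (one ratio per basic block, shallow to
#' deep). Identity shortcuts force every block output within a stage to share
#' channel indices, so each stage gets a single shared surviving output set of
#' size `width - prune_count(R_stage, width)` (with `R_stage` the largest of
#' the stage's block ratios), ranked by the summed importance of all the
#' stage's block-output convolutions plus its projection shortcut; when the
#' stem feeds stage 1 through an identity shortcut its importance joins the
#' stage-1 ranking and the stem is pruned to the same set. Each block's first
#' convolution additionally gets its own internal surviving set of size
#' `width - prune_count(R_block, width)` from its own importance. Ties break
#' toward the lower channel index.
#'
#' @param net A trained (or initialized) `cacp_net`.
#' @param schedule Ratio vector, one entry per basic block (see
#'   [default_schedule()]).
#' @param norm_kind `"l1"` (default) or `"l2"` channel importance.
#' @return A `cacp_pruning_plan`: surviving index sets, the rewritten
#'   [arch_spec()], and provenance (schedule, norm).
#' @export
make_pruning_plan <- function(net, schedule = default_schedule(),
                              norm_kind = c("l1", "l2")) {
  norm_kind <- match.arg(norm_kind)
  spec <- net$spec
  validate_schedule(schedule, spec)
  stage_sets <- vector("list", 4L)
  inner_sets <- vector("list", 4L)
  blk_offset <- c(0L, cumsum(spec$blocks_per_stage))[1:4]
  stem_coupled <- spec$stage_strides[1] == 1L &&
    spec$stem_channels == spec$stage_widths[1]
  for (s in 1:4) {
    width <- spec$stage_widths[s]
    ratios <- schedule[blk_offset[s] + seq_len(spec$blocks_per_stage[s])]
    r_stage <- max(ratios)
    keep <- width - prune_count(r_stage, width)
    agg <- numeric(width)
    for (b in seq_along(net$stages[[s]])) {
      blk <- net$stages[[s]][[b]]
      agg <- agg + channel_importance(blk$conv2, norm_kind)
      if (!is.null(blk$down_conv)) {
        agg <- agg + channel_importance(blk$down_conv, norm_kind)
      }
    }
    if (s == 1L && stem_coupled) {
      agg <- agg + channel_importance(net$stem$conv, norm_kind)
    }
    stage_sets[[s]] <- top_surviving(agg, keep)
    inner_sets[[s]] <- lapply(seq_along(net$stages[[s]]), function(b) {
      c1 <- net$stages[[s]][[b]]$conv1
      n1 <- c1$out_ch
      top_surviving(channel_importance(c1, norm_kind),
                    n1 - prune_count(ratios[b], n1))
    })
  }
  stem_set <- if (stem_coupled) stage_sets[[1]] else
    seq_len(spec$stem_channels)
  spec_after <- arch_spec(
    stem_channels = length(stem_set),
    stage_widths = vapply(stage_sets, length, integer(1)),
    blocks_per_stage = spec$blocks_per_stage,
    stage_strides = spec$stage_strides,
    num_classes = spec$num_classes,
    input_size = spec$input_size,
    attention_enabled = spec$attention_enabled,
    attention_gamma = spec$attention_gamma,
    attention_b = spec$attention_b,
    block_inner_widths = lapply(inner_sets, function(x)
      vapply(x, length, integer(1)))
  )
  structure(list(schedule = schedule, norm_kind = norm_kind,
                 stem_set = stem_set, stage_sets = stage_sets,
                 inner_sets = inner_sets,
                 spec_before = spec, spec_after = spec_after),
            class = "cacp_pruning_plan")
}

#' @export
print.cacp_pruning_plan <- function(x, ...) {
  cat("<cacp_pruning_plan>\n")
  cat("  schedule:", paste(x$schedule, collapse = ", "),
      "| norm:", x$norm_kind, "\n")
  cat("  stage widths:", paste(x$spec_before$stage_widths, collapse = ","),
      "->", paste(x$spec_after$stage_widths, collapse = ","), "\n")
  invisible(x)
}

# column indices into a conv weight matrix (layout c_in fastest, then kernel
# position) selecting input channels `in_set` of `c_in_old`
conv_col_index <- function(in_set, c_in_old, k) {
  as.vector(outer(in_set, c_in_old * (seq_len(k * k) - 1L), `+`))
}

slice_conv <- function(src, dst, out_set, in_set) {
  dst$W <- src$W[out_set, conv_col_index(in_set, src$in_ch, src$k),
                 drop = FALSE]
  invisible()
}

slice_bn <- function(src, dst, set) {
  dst$gamma <- src$gamma[set]; dst$beta <- src$beta[set]
  dst$running_mean <- src$running_mean[set]
  dst$running_var <- src$running_var[set]
  invisible()
}

#' Apply a pruning plan, producing a smaller network
#'
#' Builds a new network from the plan's rewritten spec and transfers weights
#' by index selection: conv rows/columns, batch-norm affine terms and running
#' statistics, and the head's input columns are restricted to the surviving
#' sets. Attention modules are re-created with kernel sizes recomputed from
#' the new channel counts; a kernel whose size is unchanged keeps its trained
#' weights (the shared 1D kernel is channel-count independent), otherwise it
#' is freshly initialized.
#'
#' @param net The `cacp_net` the plan was built from.
#' @param plan A `cacp_pruning_plan` from [make_pruning_plan()].
#' @param seed Seed for any re-initialized attention kernels.
#' @return A pruned `cacp_net`.
#' @export
apply_plan <- function(net, plan, seed = 0L) {
  if (!inherits(plan, "cacp_pruning_plan")) stop("not a pruning plan")
  if (!identical(unclass(net$spec), unclass(plan$spec_before))) {
    stop("plan was built for a different architecture", call. = FALSE)
  }
  out <- build_model(plan$spec_after, seed = seed)
  slice_conv(net$stem$conv, out$stem$conv, plan$stem_set, 1:3)
  slice_bn(net$stem$bn, out$stem$bn, plan$stem_set)
  if (!is.null(out$stem$att) && out$stem$att$k == net$stem$att$k) {
    out$stem$att$w <- net$stem$att$w
  }
  in_set <- plan$stem_set
  for (s in 1:4) {
    sset <- plan$stage_sets[[s]]
    for (b in seq_along(net$stages[[s]])) {
      src <- net$stages[[s]][[b]]
      dst <- out$stages[[s]][[b]]
      iset <- plan$inner_sets[[s]][[b]]
      slice_conv(src$conv1, dst$conv1, iset, in_set)
      slice_bn(src$bn1, dst$bn1, iset)
      slice_conv(src$conv2, dst$conv2, sset, iset)
      slice_bn(src$bn2, dst$bn2, sset)
      if (!is.null(src$down_conv)) {
        if (is.null(dst$down_conv)) {
          stop("plan/spec mismatch: projection shortcut disappeared in ",
               sprintf("stage%d.block%d", s, b), call. = FALSE)
        }
        slice_conv(src$down_conv, dst$down_conv, sset, in_set)
        slice_bn(src$down_bn, dst$down_bn, sset)
      }
      for (a in c("att1", "att2")) {
        if (!is.null(dst[[a]]) && dst[[a]]$k == src[[a]]$k) {
          dst[[a]]$w <- src[[a]]$w
        }
      }
      in_set <- sset
    }
  }
  out$head$W <- net$head$W[, plan$stage_sets[[4]], drop = FALSE]
  out$head$b <- net$head$b
  out
}

#' Serialize / parse a pruning plan as JSON
#'
#' The plan (schedule, norm kind, surviving index lists and resulting spec) is
#' stored so a prune is reproducible and auditable.
#'
#' @param plan A `cacp_pruning_plan`.
#' @return `serialize_pruning_plan()`: JSON text; `parse_pruning_plan()`: a
#'   plan.
#' @export
serialize_pruning_plan <- function(plan) {
  jsonlite::toJSON(list(
    schedule = plan$schedule, norm_kind = plan$norm_kind,
    stem_set = plan$stem_set, stage_sets = plan$stage_sets,
    inner_sets = plan$inner_sets,
    spec_before = jsonlite::fromJSON(serialize_spec(plan$spec_before)),
    spec_after = jsonlite::fromJSON(serialize_spec(plan$spec_after))
  ), auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname serialize_pruning_plan
#' @param text JSON produced by `serialize_pruning_plan()`.
#' @export
parse_pruning_plan <- function(text) {
  x <- jsonlite::fromJSON(text, simplifyVector = TRUE)
  restore_spec <- function(y) parse_spec(jsonlite::toJSON(y, auto_unbox = TRUE,
                                                          digits = NA))
  inner <- x$inner_sets
  if (!is.list(inner)) inner <- apply(inner, 1, identity, simplify = FALSE)
  inner <- lapply(inner, function(st) {
    if (is.list(st)) lapply(st, as.integer)
    else if (is.matrix(st)) apply(st, 1, as.integer, simplify = FALSE)
    else list(as.integer(st))
  })
  stage_sets <- x$stage_sets
  if (!is.list(stage_sets)) {
    stage_sets <- apply(stage_sets, 1, identity, simplify = FALSE)
  }
  structure(list(schedule = as.numeric(x$schedule), norm_kind = x$norm_kind,
                 stem_set = as.integer(x$stem_set),
                 stage_sets = lapply(stage_sets, as.integer),
                 inner_sets = inner,
                 spec_before = restore_spec(x$spec_before),
                 spec_after = restore_spec(x$spec_after)),
            class = "cacp_pruning_plan")
}
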