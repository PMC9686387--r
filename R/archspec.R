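#' Architecture specification for the residual backbone
#'
#' An `arch_spec` is a portable, serializable description of an 18-layer-style
#' residual classifier: stem width, the four stage widths, blocks per stage,
#' stage strides, head size and whether the channel-attention module is
#' attached. It is the single source of truth for building, profiling and
#' pruning models: structured pruning rewrites the spec rather than masking
#' weights, so pruned variants are first-class architectures.
#'
#' `block_inner_widths` optionally narrows the first convolution inside each
#' basic block independently of the stage (block-output) width; pruning plans
#' with per-block ratios produce such specs. `NULL` means "equal to the stage
#' width".
#'
#' @param stem_channels Output channels of the 7x7 stem convolution.
#' @param stage_widths Integer vector of 4 stage (block-output) widths.
#' @param blocks_per_stage Integer vector of 4 basic-block counts.
#' @param stage_strides Integer vector of 4 strides for the first block of
#'   each stage.
#' @param num_classes Number of output classes of the linear head.
#' @param input_size Expected square input resolution in pixels.
#' @param attention_enabled Attach the improved channel-attention module after
#'   every 3x3 convolution (stem included)?
#' @param attention_gamma,attention_b Parameters of the channel-to-kernel-size
#'   mapping used by the attention module (see
#'   [kernel_size_from_channels()]).
#' @param block_inner_widths `NULL`, or a list of 4 integer vectors giving the
#'   output width of the first convolution of each block.
#' @return An object of class `cacp_spec`.
#' @examples
#' spec <- arch_spec(num_classes = 5)
#' spec
#' @export
arch_spec <- function(stem_channels = 64L,
                      stage_widths = c(64L, 128L, 256L, 512L),
                      blocks_per_stage = c(2L, 2L, 2L, 2L),
                      stage_strides = c(1L, 2L, 2L, 2L),
                      num_classes = 5L,
                      input_size = 224L,
                      attention_enabled = FALSE,
                      attention_gamma = 2,
                      attention_b = 1,
                      block_inner_widths = NULL) {
  spec <- structure(
    list(
      stem_channels = as.integer(stem_channels),
      stage_widths = as.integer(stage_widths),
      blocks_per_stage = as.integer(blocks_per_stage),
      stage_strides = as.integer(stage_strides),
      num_classes = as.integer(num_classes),
      input_size = as.integer(input_size),
      attention_enabled = isTRUE(attention_enabled),
      attention_gamma = as.numeric(attention_gamma),
      attention_b = as.numeric(attention_b),
      block_inner_widths = normalize_inner_widths(block_inner_widths,
                                                  as.integer(stage_widths),
                                                  as.integer(blocks_per_stage))
    ),
    class = "cacp_spec"
  )
  validate_spec(spec)
  spec
}

#' Validate an architecture spec
#'
#' Checks every field's type and range; errors name the offending field.
#'
#' @param spec An object created by [arch_spec()] or [parse_spec()].
#' @return The spec, invisibly, if valid.
#' @export
validate_spec <- function(spec) {
  if (!inherits(spec, "cacp_spec")) stop("not a 'cacp_spec' object")
  chk_pos_int <- function(x, field, len = 1L) {
    if (length(x) != len || anyNA(x) || any(x < 1L)) {
      stop(sprintf("invalid field '%s': expected %d positive integer(s)",
                   field, len), call. = FALSE)
    }
  }
  chk_pos_int(spec$stem_channels, "stem_channels")
  chk_pos_int(spec$stage_widths, "stage_widths", 4L)
  chk_pos_int(spec$blocks_per_stage, "blocks_per_stage", 4L)
  if (length(spec$stage_strides) != 4L || any(!spec$stage_strides %in% 1:2)) {
    stop("invalid field 'stage_strides': expected 4 strides in {1,2}",
         call. = FALSE)
  }
  chk_pos_int(spec$num_classes, "num_classes")
  chk_pos_int(spec$input_size, "input_size")
  if (spec$input_size < 32L) {
    stop("invalid field 'input_size': must be >= 32", call. = FALSE)
  }
  if (!is.null(spec$block_inner_widths)) {
    if (length(spec$block_inner_widths) != 4L) {
      stop("invalid field 'block_inner_widths': expected a list of 4 vectors",
           call. = FALSE)
    }
    for (s in 1:4) {
      chk_pos_int(spec$block_inner_widths[[s]],
                  sprintf("block_inner_widths[[%d]]", s),
                  spec$blocks_per_stage[s])
    }
  }
  invisible(spec)
}

#' @export
print.cacp_spec <- function(x, ...) {
  cat("<cacp_spec>\n")
  cat("  stem:", x$stem_channels, "channels (7x7, stride 2) + 3x3 max pool\n")
  for (s in 1:4) {
    inner <- block_inner(x, s)
    cat(sprintf("  stage %d: width %d, %d block(s), stride %d, inner [%s]\n",
                s, x$stage_widths[s], x$blocks_per_stage[s],
                x$stage_strides[s], paste(inner, collapse = ",")))
  }
  cat("  head:", x$num_classes, "classes | input:",
      x$input_size, "px | attention:",
      if (x$attention_enabled) "on" else "off", "\n")
  invisible(x)
}

# inner widths equal to the stage widths are the default; store NULL so that
# equivalent specs compare and serialize identically
normalize_inner_widths <- function(biw, stage_widths, blocks_per_stage) {
  if (is.null(biw)) return(NULL)
  biw <- unname(lapply(biw, function(x) as.integer(unname(x))))
  all_default <- length(biw) == 4L &&
    all(vapply(1:4, function(s) {
      length(biw[[s]]) == blocks_per_stage[s] &&
        all(biw[[s]] == stage_widths[s])
    }, logical(1)))
  if (all_default) NULL else biw
}

# inner (conv1) widths of stage s, defaulting to the stage width
block_inner <- function(spec, s) {
  if (is.null(spec$block_inner_widths)) {
    rep(spec$stage_widths[s], spec$blocks_per_stage[s])
  } else {
    spec$block_inner_widths[[s]]
  }
}

#' Preset specs
#'
#' `spec_peanut()` is the 5-class configuration used for peanut leaf disease
#' (healthy, scorch, rust, scorch+rust, leaf spot); `spec_plantvillage()` is
#' the 38-class PlantVillage configuration. Both are the standard 18-layer
#' residual design.
#'
#' @param attention_enabled Attach the channel-attention module?
#' @param input_size Input resolution in pixels.
#' @return A `cacp_spec`.
#' @export
spec_peanut <- function(attention_enabled = FALSE, input_size = 224L) {
  arch_spec(num_classes = 5L, attention_enabled = attention_enabled,
            input_size = input_size)
}

#' @rdname spec_peanut
#' @export
spec_plantvillage <- function(attention_enabled = FALSE, input_size = 224L) {
  arch_spec(num_classes = 38L, attention_enabled = attention_enabled,
            input_size = input_size)
}

#' Serialize / parse an architecture spec
#'
#' Specs round-trip losslessly through a compact JSON text form; the same form
#' is written as the sidecar file next to every checkpoint so pruned models
#' reload without shape inference.
#'
#' @param spec A `cacp_spec`.
#' @return `serialize_spec()`: a JSON string. `parse_spec()`: a `cacp_spec`.
#' @export
serialize_spec <- function(spec) {
  validate_spec(spec)
  x <- unclass(spec)
  if (is.null(x$block_inner_widths)) x$block_inner_widths <- NULL
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}

#' @rdname serialize_spec
#' @param text JSON text produced by [serialize_spec()].
#' @export
parse_spec <- function(text) {
  x <- tryCatch(jsonlite::fromJSON(text, simplifyVector = TRUE),
                error = function(e) {
                  stop("malformed spec text: ", conditionMessage(e),
                       call. = FALSE)
                })
  required <- c("stem_channels", "stage_widths", "blocks_per_stage",
                "stage_strides", "num_classes", "input_size")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("spec text missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  biw <- x$block_inner_widths
  if (!is.null(biw) && !is.list(biw)) biw <- as.list(as.data.frame(t(biw)))
  arch_spec(
    stem_channels = x$stem_channels,
    stage_widths = x$stage_widths,
    blocks_per_stage = x$blocks_per_stage,
    stage_strides = x$stage_strides,
    num_classes = x$num_classes,
    input_size = x$input_size,
    attention_enabled = isTRUE(x$attention_enabled),
    attention_gamma = x$attention_gamma %||% 2,
    attention_b = x$attention_b %||% 1,
    block_inner_widths = biw
  )
}

#' @rdname serialize_spec
#' @param path File to write to / read from.
#' @export
write_spec <- function(spec, path) {
  writeLines(serialize_spec(spec), path)
  invisible(path)
}

#' @rdname serialize_spec
#' @export
read_spec <- function(path) {
  parse_spec(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
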