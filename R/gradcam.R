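valid_gradcam_layers <- function(net) {
  nm <- names(net_layers(net))
  nm[grepl("conv", nm) & !grepl("down", nm)]
}

resolve_layer <- function(net, layer) {
  if (identical(layer, "stem.conv")) {
    net$stem$capture_at <- "conv"
    return(net$stem)
  }
  m <- regmatches(layer,
                  regexec("^stage([0-9]+)\\.block([0-9]+)\\.(conv[12])$",
                          layer))[[1]]
  if (length(m) != 4L) {
    stop("invalid layer '", layer, "'; valid layers: ",
         paste(valid_gradcam_layers(net), collapse = ", "), call. = FALSE)
  }
  s <- as.integer(m[2]); b <- as.integer(m[3])
  if (s > 4L || b > length(net$stages[[s]])) {
    stop("invalid layer '", layer, "'; valid layers: ",
         paste(valid_gradcam_layers(net), collapse = ", "), call. = FALSE)
  }
  blk <- net$stages[[s]][[b]]
  blk$capture_at <- m[4]
  blk
}

#' Gradient-weighted class activation heatmap
#'
#' Computes the Grad-CAM heatmap of a target class at a chosen convolution:
#' the gradient of the class logit is backpropagated to that convolution's
#' output, each activation map is weighted by its spatially averaged gradient,
#' the weighted sum is rectified, bilinearly upsampled to the input
#' resolution, and min-max normalized to `[0,1]` (a constant map — e.g. from
#' degenerate activations — normalizes to all zeros). Dark/high values mark
#' the spatial evidence the model uses for the class.
#'
#' @param net A `cacp_net`.
#' @param image One standardized H x W x 3 array.
#' @param target_class Class index (1-based) or, with `classes` given, a
#'   label.
#' @param layer Convolution name such as `"stage4.block2.conv2"` (the
#'   default: the last stage's final conv). Invalid names raise an error
#'   listing the valid layers.
#' @param classes Optional class labels for `target_class` lookup.
#' @return An H x W matrix in `[0,1]` matching the input's spatial shape.
#' @export
gradcam <- function(net, image, target_class, layer = NULL, classes = NULL) {
  if (!is.null(classes) && is.character(target_class)) {
    target_class <- match(target_class, classes)
  }
  k <- net$spec$num_classes
  if (is.na(target_class) || target_class < 1L || target_class > k) {
    stop("target_class out of range", call. = FALSE)
  }
  layer <- layer %||% sprintf("stage4.block%d.conv2",
                              length(net$stages[[4]]))
  holder <- resolve_layer(net, layer)
  on.exit({
    holder$capture_at <- NULL
    holder$captured <- NULL
    holder$captured_grad <- NULL
  })
  fm <- images_to_fmap(list(image))
  z <- net_forward(net, fm, training = FALSE, cache = TRUE)
  dz <- matrix(0, k, 1)
  dz[target_class, 1] <- 1
  net_backward(net, dz)
  act <- holder$captured
  grad <- holder$captured_grad
  alpha <- rowMeans(grad$x)                    # one weight per channel
  map <- colSums(act$x * alpha)                # weighted sum over channels
  map <- matrix(pmax(map, 0), act$H, act$W)    # rectify
  up <- bilinear_resize(array(map, c(act$H, act$W, 1)),
                        dim(image)[1], dim(image)[2])[, , 1]
  rng <- range(up)
  if (diff(rng) < 1e-12) {
    matrix(0, dim(image)[1], dim(image)[2])
  } else {
    (up - rng[1]) / diff(rng)
  }
}
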