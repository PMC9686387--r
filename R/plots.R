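#' Plot a training history
#'
#' @param history The `history` data.frame of a [train()] fit.
#' @return A ggplot object with loss and accuracy per epoch.
#' @export
plot_history <- function(history) {
  long <- rbind(
    data.frame(epoch = history$epoch, value = history$loss, metric = "loss"),
    data.frame(epoch = history$epoch, value = history$accuracy,
               metric = "accuracy"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' @param report A `cacp_eval`.
#' @return A ggplot tile plot (rows = true class).
#' @export
plot_confusion <- function(report) {
  df <- as.data.frame(report$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$truth))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' Plot one-vs-rest ROC curves
#'
#' @param report A `cacp_eval` with ROC data.
#' @return A ggplot object, one curve per class with AUC in the legend.
#' @export
plot_roc <- function(report) {
  if (is.null(report$roc)) stop("report carries no ROC data", call. = FALSE)
  df <- do.call(rbind, lapply(names(report$roc), function(cls) {
    r <- report$roc[[cls]]
    data.frame(fpr = r$roc$fpr, tpr = r$roc$tpr,
               class = sprintf("%s (AUC %.3f)", cls, r$auc))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   color = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(linetype = "dashed", color = "grey") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Render a Grad-CAM heatmap over its image
#'
#' @param image The H x W x 3 input image in `[0,1]` (de-standardized).
#' @param heat The heatmap from [gradcam()].
#' @param alpha Overlay opacity.
#' @return A ggplot raster of the image with the heatmap overlaid in red.
#' @export
plot_gradcam <- function(image, heat, alpha = 0.45) {
  H <- dim(image)[1]; W <- dim(image)[2]
  base <- grDevices::rgb(pmin(pmax(image[, , 1], 0), 1),
                         pmin(pmax(image[, , 2], 0), 1),
                         pmin(pmax(image[, , 3], 0), 1))
  df <- expand.grid(h = seq_len(H), w = seq_len(W))
  df$fill <- base
  df$heat <- as.vector(heat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$w, y = .data$h)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$heat), fill = "red") +
    ggplot2::scale_alpha(range = c(0, alpha), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
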