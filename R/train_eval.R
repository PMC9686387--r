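#' Training hyperparameters
#'
#' Defaults follow the published recipe: stochastic gradient descent with
#' batch size 32, weight decay 0.001, learning rate 5e-4 and cross-entropy
#' loss (200-epoch and 400-epoch presets correspond to the PlantVillage and
#' peanut schedules). Momentum (0.9) and the constant learning rate are
#' configurable additions the recipe leaves open.
#'
#' @param batch_size Mini-batch size.
#' @param weight_decay L2 penalty applied to conv and linear weights.
#' @param learning_rate Constant SGD step size.
#' @param momentum SGD momentum.
#' @param epochs Number of passes over the training set.
#' @param seed Seed controlling data order (and any augmentation).
#' @return A `cacp_hyperparams`.
#' @export
hyperparams <- function(batch_size = 32L, weight_decay = 1e-3,
                        learning_rate = 5e-4, momentum = 0.9,
                        epochs = 200L, seed = 1L) {
  stopifnot(batch_size >= 1, weight_decay >= 0, learning_rate >= 0,
            momentum >= 0, epochs >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 learning_rate = learning_rate, momentum = momentum,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "cacp_hyperparams")
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# mean cross-entropy over a batch and its gradient w.r.t. the logits
cross_entropy <- function(z, y) {
  n <- ncol(z)
  p <- softmax_cols(z)
  at <- cbind(y, seq_len(n))
  loss <- -mean(log(pmax(p[at], 1e-12)))
  dz <- p
  dz[at] <- dz[at] - 1
  list(loss = loss, dz = dz / n)
}

#' Train a network with mini-batch SGD
#'
#' Runs `hp$epochs` epochs of seeded mini-batch stochastic gradient descent
#' with cross-entropy loss, recording mean loss and top-1 accuracy per epoch.
#' The network's layer parameters are updated in place; the same (now trained)
#' network is also returned inside the fit object.
#'
#' @param net A `cacp_net` whose class count matches the data.
#' @param train_set A standardized `leaf_image_set`.
#' @param hp A [hyperparams()].
#' @param verbose Print one line per epoch?
#' @return A `cacp_fit`: `list(net, history, hp)` with `history` a data.frame
#'   of epoch, loss and accuracy.
#' @export
train <- function(net, train_set, hp = hyperparams(), verbose = FALSE) {
  classes <- train_set$classes
  if (length(classes) != net$spec$num_classes) {
    stop("network has ", net$spec$num_classes, " classes but the data has ",
         length(classes), call. = FALSE)
  }
  y_all <- match(train_set$labels, classes)
  n <- length(train_set$images)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_seed(hp$seed, {
    for (ep in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      tot_loss <- 0; correct <- 0L
      for (start in seq(1L, n, by = hp$batch_size)) {
        idx <- ord[start:min(start + hp$batch_size - 1L, n)]
        fm <- images_to_fmap(train_set$images[idx])
        y <- y_all[idx]
        z <- net_forward(net, fm, training = TRUE, cache = TRUE)
        ce <- cross_entropy(z, y)
        tot_loss <- tot_loss + ce$loss * length(idx)
        correct <- correct + sum(max.col(t(z)) == y)
        net_backward(net, ce$dz)
        for (ly in net_layers(net)) {
          layer_step(ly, hp$learning_rate, hp$momentum, hp$weight_decay)
        }
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = tot_loss / n, accuracy = correct / n))
      if (verbose) {
        message(sprintf("epoch %3d | loss %.4f | acc %.3f",
                        ep, tot_loss / n, correct / n))
      }
    }
  })
  structure(list(net = net, history = history, hp = hp), class = "cacp_fit")
}

#' @export
print.cacp_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<cacp_fit> %d epoch(s); final loss %.4f, train accuracy %.3f\n",
              nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}

#' Classification metrics from one-vs-rest confusion counts
#'
#' `accuracy = (TP+TN)/(TP+FP+TN+FN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`, `F1 = 2*precision*recall/(precision+recall)`;
#' undefined ratios (zero denominators) are reported as 0.
#'
#' @param tp,tn,fp,fn Confusion counts.
#' @return A named list with accuracy, precision, recall and f1.
#' @examples
#' metrics_from_counts(9, 8, 1, 2)$accuracy  # 0.85
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  safe_div <- function(a, b) if (b > 0) a / b else 0
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  list(accuracy = safe_div(tp + tn, tp + fp + tn + fn),
       precision = precision, recall = recall,
       f1 = safe_div(2 * precision * recall, precision + recall))
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps a threshold over that class's scores (probabilities
#' or logits), tracing true/false positive rates; AUC is computed by the
#' trapezoidal rule. A class with no positive or no negative examples has an
#' undefined ROC and raises an error.
#'
#' @param scores Numeric matrix, one row per sample and one column per class.
#' @param labels Character/factor vector of true labels.
#' @param classes Class order matching the score columns (default: column
#'   names, falling back to sorted unique labels).
#' @return A named list per class: `list(roc = data.frame(fpr, tpr), auc =)`.
#' @export
roc_auc <- function(scores, labels, classes = NULL) {
  classes <- classes %||% colnames(scores) %||% sort(unique(as.character(labels)))
  labels <- as.character(labels)
  out <- list()
  for (j in seq_along(classes)) {
    pos <- labels == classes[j]
    if (all(pos) || !any(pos)) {
      stop("AUC undefined for class '", classes[j],
           "': labels contain a single class", call. = FALSE)
    }
    s <- scores[, j]
    ord <- order(-s)
    pos_o <- pos[ord]
    tp <- cumsum(pos_o); fp <- cumsum(!pos_o)
    # collapse threshold ties to the last point of each tied run
    keep <- c(diff(s[ord]) != 0, TRUE)
    tpr <- c(0, tp[keep] / sum(pos))
    fpr <- c(0, fp[keep] / sum(!pos))
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    out[[classes[j]]] <- list(roc = data.frame(fpr = fpr, tpr = tpr),
                              auc = auc)
  }
  out
}

#' Evaluate a network on a labeled test set
#'
#' Argmax predictions, the K x K confusion matrix (rows = true class), per
#' class one-vs-rest counts and metrics, their macro averages, overall top-1
#' accuracy and per-class ROC/AUC.
#'
#' @param net A `cacp_net`.
#' @param test_set A standardized `leaf_image_set` (never augmented).
#' @param batch_size Forward-pass batch size.
#' @return A `cacp_eval`: confusion matrix, `per_class` data.frame, `accuracy`,
#'   macro precision/recall/F1, and `roc`.
#' @export
evaluate <- function(net, test_set, batch_size = 32L) {
  if (!length(test_set$images)) stop("empty test set", call. = FALSE)
  classes <- test_set$classes
  probs <- predict_batch(net, test_set$images, type = "prob",
                         batch_size = batch_size)
  colnames(probs) <- classes
  pred <- classes[max.col(probs, ties.method = "first")]
  eval_report(test_set$labels, pred, probs, classes)
}

#' Build an evaluation report from labels, predictions and scores
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param probs Optional score matrix (samples x classes) for ROC/AUC.
#' @param classes Class order.
#' @return A `cacp_eval`.
#' @export
eval_report <- function(truth, pred, probs = NULL,
                        classes = sort(unique(truth))) {
  truth <- factor(truth, levels = classes)
  pred <- factor(pred, levels = classes)
  cm <- table(truth = truth, pred = pred)
  total <- sum(cm)
  per <- lapply(seq_along(classes), function(j) {
    tp <- cm[j, j]
    fp <- sum(cm[-j, j])
    fn <- sum(cm[j, -j])
    tn <- total - tp - fp - fn
    m <- metrics_from_counts(tp, tn, fp, fn)
    data.frame(class = classes[j], tp = tp, tn = tn, fp = fp, fn = fn,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  per <- do.call(rbind, per)
  roc <- NULL
  if (!is.null(probs)) {
    roc <- tryCatch(roc_auc(probs, as.character(truth), classes),
                    error = function(e) {
                      warning(conditionMessage(e), call. = FALSE)
                      NULL
                    })
    per$auc <- if (!is.null(roc)) {
      vapply(roc, function(r) r$auc, numeric(1))
    } else NA_real_
  }
  structure(list(confusion = cm, per_class = per,
                 accuracy = sum(diag(cm)) / total,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 n = total, roc = roc),
            class = "cacp_eval")
}

#' @export
print.cacp_eval <- function(x, ...) {
  cat(sprintf("<cacp_eval> n=%d | accuracy %.4f | macro F1 %.4f\n",
              x$n, x$accuracy, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @export
as.data.frame.cacp_eval <- function(x, ...) x$per_class

#' Write an evaluation report as JSON and CSV
#'
#' @param report A `cacp_eval`.
#' @param path_json,path_csv Output paths (`NULL` to skip).
#' @return The report, invisibly.
#' @export
write_eval <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      accuracy = report$accuracy,
      macro_precision = report$macro_precision,
      macro_recall = report$macro_recall,
      macro_f1 = report$macro_f1,
      n = report$n,
      confusion = as.matrix(unclass(report$confusion)),
      per_class = report$per_class
    ), path_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(path_csv)) {
    utils::write.csv(report$per_class, path_csv, row.names = FALSE)
  }
  invisible(report)
}
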