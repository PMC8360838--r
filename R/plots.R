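#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline geom_point
#'   geom_step facet_wrap labs theme_minimal vars
#' @export
ggplot2::autoplot

#' Plot a paired electrogram record
#'
#' Unipolar and bipolar traces in stacked facets, optionally with
#' ground-truth activation times marked.
#'
#' @param object An `egm_record`.
#' @param truth Optional `egm_truth`; activation times are drawn as vertical
#'   lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.egm_record <- function(object, truth = NULL, ...) {
  df <- tidy.egm_record(object)
  p <- ggplot(df, aes(x = .data$t_ms, y = .data$mv)) +
    geom_line(linewidth = 0.3) +
    facet_wrap(vars(.data$channel), ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = "amplitude (mV)",
         title = object$record_id) +
    theme_minimal()
  if (!is.null(truth) && length(truth$activation_times)) {
    p <- p + geom_vline(xintercept = truth$activation_times,
                        colour = "red", linetype = "dashed",
                        linewidth = 0.2)
  }
  p
}

#' Plot an importance trace
#'
#' @param object An `importance_trace`.
#' @param truth_onsets Optional onset times (ms) drawn as vertical lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.importance_trace <- function(object, truth_onsets = NULL, ...) {
  df <- tidy.importance_trace(object)
  p <- ggplot(df, aes(x = .data$t_ms, y = .data$importance)) +
    geom_line(colour = "steelblue") +
    labs(x = "time (ms)", y = "normalized importance",
         title = sprintf("Grad-CAM importance (%s)", object$layer_id)) +
    theme_minimal()
  if (!is.null(truth_onsets) && length(truth_onsets)) {
    p <- p + geom_vline(xintercept = truth_onsets, colour = "red",
                        linetype = "dashed", linewidth = 0.2)
  }
  p
}

#' ROC curve plot
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @return A ggplot of the empirical ROC curve.
#' @export
plot_roc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[ord] == 1) / sum(labels == 1)
  fpr <- cumsum(labels[ord] == 0) / sum(labels == 0)
  df <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot(df, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("ROC (AUC = %.3f)",
                         auc_rank(scores, labels))) +
    theme_minimal()
}

#' Training history plot
#'
#' @param model A trained `fast_cnn`.
#' @return A ggplot of per-epoch loss and validation AUC.
#' @export
plot_history <- function(model) {
  df <- tidyr::pivot_longer(model$history,
                            c("train_loss", "val_auc"),
                            names_to = "metric", values_to = "value")
  ggplot(df, aes(x = .data$epoch, y = .data$value)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(vars(.data$metric), ncol = 1, scales = "free_y") +
    labs(x = "epoch", y = NULL) +
    theme_minimal()
}
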