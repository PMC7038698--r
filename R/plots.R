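#' Plot a confusion matrix as a tile heat map
#'
#' @param object A `zs_confusion` object.
#' @param ... Unused.
#' @return A ggplot object (rows = truth, columns = predicted).
#' @method autoplot zs_confusion
#' @export
autoplot.zs_confusion <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(object$labels)) +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "predicted", y = "truth",
                  title = "Zero-shot confusion matrix")
}

#' Plot a class correlation matrix
#'
#' @param object A `zs_correlation` object.
#' @param ... Unused.
#' @return A ggplot tile map of the pairwise coefficients.
#' @method autoplot zs_correlation
#' @export
autoplot.zs_correlation <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class_a, y = .data$class_b,
                                   fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$coefficient)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Class %s matrix", object$method))
}

#' Plot the training loss curve of a network
#'
#' @param object A trained `zeroshot_network`.
#' @param ... Unused.
#' @return A ggplot line plot of per-epoch loss.
#' @method autoplot zeroshot_network
#' @export
autoplot.zeroshot_network <- function(object, ...) {
  hist <- tidy(object)
  if (nrow(hist) == 0) abort("network has no training history yet.")
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss",
                  title = "Training loss")
}

#' Plot per-class metrics of a report
#'
#' @param object A `zs_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot bar chart of precision, recall and F-measure per class.
#' @method autoplot zs_report
#' @export
autoplot.zs_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$metrics[, c("class", "precision", "recall", "f_measure")],
    cols = -"class", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-class zero-shot metrics")
}
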