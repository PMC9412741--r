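#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_point
#'   geom_text scale_fill_gradient labs theme_minimal facet_wrap
NULL

#' Plot training/validation curves
#'
#' @param object An `"elytra_cnn"` with a non-empty history.
#' @param ... Unused.
#' @return A ggplot: loss and accuracy per epoch for both streams.
#' @method autoplot elytra_cnn
#' @export
autoplot.elytra_cnn <- function(object, ...) {
  h <- object$history
  stopifnot(nrow(h) > 0)
  long <- dplyr::bind_rows(
    tibble(epoch = h$epoch, stream = "train", metric = "loss", value = h$train_loss),
    tibble(epoch = h$epoch, stream = "validation", metric = "loss", value = h$val_loss),
    tibble(epoch = h$epoch, stream = "train", metric = "accuracy", value = h$train_accuracy),
    tibble(epoch = h$epoch, stream = "validation", metric = "accuracy", value = h$val_accuracy)
  )
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$stream)) +
    geom_line() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL,
         title = "Training and validation progress") +
    theme_minimal()
}

#' Plot a row-percent confusion matrix
#'
#' Rows are true species, columns predicted species; each cell shows the
#' percentage of the true class's tiles predicted as that column, so the
#' diagonal is the per-species accuracy.
#'
#' @param object An `"elytra_confusion"`.
#' @param label_cells Print percentages inside cells (sensible for small
#'   K).
#' @param ... Unused.
#' @return A ggplot heatmap.
#' @method autoplot elytra_confusion
#' @export
autoplot.elytra_confusion <- function(object, label_cells = length(object$class_order) <= 10, ...) {
  df <- tidy(object)
  df$true <- factor(df$true, levels = rev(object$class_order))
  df$predicted <- factor(df$predicted, levels = object$class_order)
  p <- ggplot(df, aes(x = .data$predicted, y = .data$true, fill = .data$percent)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 100)) +
    labs(x = "predicted species", y = "true species", fill = "% of row",
         title = "Row-percent confusion matrix") +
    theme_minimal()
  if (label_cells) {
    p <- p + geom_text(aes(label = sprintf("%.0f", .data$percent)), size = 3)
  }
  p
}

#' Scatter a 2-D feature embedding
#'
#' @param embedding A tibble from [embed_2d()].
#' @return A ggplot of the embedded tiles colored by label.
#' @export
plot_embedding <- function(embedding) {
  ggplot(embedding, aes(x = .data$x, y = .data$y, colour = .data$label)) +
    geom_point(alpha = 0.7) +
    labs(title = "Feature-layer embedding", colour = "species") +
    theme_minimal()
}

#' Bar chart of per-species metrics
#'
#' @param metrics A [compute_metrics()] tibble.
#' @return A ggplot with one panel per metric.
#' @export
plot_metrics <- function(metrics) {
  long <- tidyr_longer(metrics)
  ggplot(long, aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    facet_wrap(~metric, ncol = 1) +
    labs(x = NULL, y = NULL, title = "Per-species prediction metrics") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

# minimal pivot (avoids a tidyr dependency for one call site)
tidyr_longer <- function(metrics) {
  dplyr::bind_rows(lapply(c("precision", "recall", "specificity", "mcc"), function(mname) {
    tibble(class = metrics$class, metric = mname, value = metrics[[mname]])
  }))
}
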