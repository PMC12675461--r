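# Plot and tidier methods for the package's result types.

#' Tidy a training history
#'
#' @param x A `sobelnet_history`.
#' @param ... Unused.
#' @return Long tibble: `epoch`, `metric`, `split`, `value`.
#' @export
tidy.sobelnet_history <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"epoch",
    names_to = "metric", values_to = "value") |>
    dplyr::mutate(
      split = ifelse(grepl("^val_", .data$metric), "validation", "training"),
      metric = sub("^val_", "", .data$metric)
    )
}

#' One-row summary of a training run
#'
#' @param x A `sobelnet_history`.
#' @param ... Unused.
#' @return Tibble with final/best epoch statistics.
#' @export
glance.sobelnet_history <- function(x, ...) {
  tibble(
    epochs_run = nrow(x),
    best_epoch = attr(x, "best_epoch") %||% which.min(x$val_loss),
    final_loss = tail(x$loss, 1), final_accuracy = tail(x$accuracy, 1),
    final_val_loss = tail(x$val_loss, 1),
    final_val_accuracy = tail(x$val_accuracy, 1),
    final_lr = tail(x$lr, 1)
  )
}

#' Plot accuracy and loss by epoch
#'
#' @param object A `sobelnet_history`.
#' @param ... Unused.
#' @return A ggplot: one facet per metric, one line per split.
#' @export
autoplot.sobelnet_history <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$metric %in% c("accuracy", "loss"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
    colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an attribution heatmap
#'
#' @param object A `sobelnet_attribution`.
#' @param ... Unused.
#' @return A ggplot raster of the relevance map.
#' @export
autoplot.sobelnet_attribution <- function(object, ...) {
  H <- nrow(object); W <- ncol(object)
  df <- tibble(
    row = rep(seq_len(H), times = W),
    col = rep(seq_len(W), each = H),
    relevance = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
    fill = .data$relevance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (class %s)", attr(object, "method"),
      attr(object, "target_class")), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-class ROC curves from an evaluation report
#'
#' @param object A `sobelnet_report`.
#' @param ... Unused.
#' @return A ggplot of the one-vs-rest ROC curves with the chance diagonal.
#' @export
autoplot.sobelnet_report <- function(object, ...) {
  df <- dplyr::bind_rows(object$roc)
  labs <- sprintf("%s (AUC %.2f)", names(object$per_class_auc),
    object$per_class_auc)
  names(labs) <- names(object$per_class_auc)
  df$class <- labs[df$class]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
    colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
      colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
      colour = NULL) +
    ggplot2::theme_minimal()
}
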