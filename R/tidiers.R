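#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted multimodal classifier
#'
#' One row per component with its parameter count.
#'
#' @param x a `sow_fit` from [train_model()].
#' @param ... unused.
#' @return tibble with `component`, `n_params`.
#' @export
tidy.sow_fit <- function(x, ...) {
  m <- x$model
  tibble::tibble(
    component = c("image_encoder", "audio_encoder", "fusion", "backbone"),
    n_params = c(count_params(m$image_enc), count_params(m$audio_enc),
                 count_params(m$fusion), count_params(m$backbone))
  )
}

#' One-row summary of a fitted multimodal classifier
#'
#' @param x a `sow_fit`.
#' @param ... unused.
#' @return tibble with the epochs run, best epoch, best validation
#'   loss, final learning rate and total parameter count.
#' @export
glance.sow_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    best_val_loss = min(h$val_loss),
    final_train_loss = h$train_loss[nrow(h)],
    final_lr = h$lr[nrow(h)],
    n_params = sum(tidy.sow_fit(x)$n_params)
  )
}

#' @export
print.sow_fit <- function(x, ...) {
  g <- glance.sow_fit(x)
  cat(sprintf(
    "<sow_fit> %d epochs (best %d), best val loss %.4f, %d parameters\n",
    g$epochs, g$best_epoch, g$best_val_loss, g$n_params))
  invisible(x)
}

#' Plot training and validation loss curves
#'
#' @param object a `sow_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sow_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ablation table
#'
#' Bar chart of precision/recall/F1 per fusion condition.
#'
#' @param tbl a [run_ablation()] tibble.
#' @return a ggplot.
#' @export
plot_ablation <- function(tbl) {
  long <- tidyr::pivot_longer(tbl, c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "percent", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Display a thermal image matrix
#'
#' @param img numeric matrix.
#' @param main title.
#' @return a ggplot.
#' @export
plot_thermal <- function(img, main = NULL) {
  df <- tidyr::expand_grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- img[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = main, x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
}
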