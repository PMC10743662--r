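#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a training run
#'
#' One row per epoch: train loss, validation loss, validation mean AUC
#' and learning rate.
#'
#' @param x A `window_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy window_fit
#' @export
tidy.window_fit <- function(x, ...) x$log

#' One-row summary of a training run
#'
#' @param x A `window_fit`.
#' @param ... Unused.
#' @return Tibble with mode, epochs run, selected checkpoint epoch and
#'   its validation loss and mean AUC, and the final learning rate.
#' @method glance window_fit
#' @export
glance.window_fit <- function(x, ...) {
  sel <- x$selected_epoch
  tibble::tibble(
    mode = x$model_config$mode,
    n_epochs = nrow(x$log),
    selected_epoch = sel,
    val_loss = x$log$val_loss[sel],
    val_mean_auc = x$log$val_mean_auc[sel],
    final_lr = x$log$lr[nrow(x$log)]
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-class tibble (`class`, `auc`, `ci_low`, `ci_high`,
#'   `n_defined`).
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "eval_report")
  out
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with the mean AUC over defined classes, the number of
#'   defined classes, images and bootstrap resamples.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    mean_auc = attr(x, "mean_auc"),
    n_classes = sum(!is.na(x$auc)),
    n_images = attr(x, "n_images"),
    n_resamples = attr(x, "n_resamples")
  )
}

#' Plot training curves
#'
#' Train/validation loss and validation mean AUC per epoch, with the
#' selected checkpoint marked.
#'
#' @param object A `window_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot window_fit
#' @export
autoplot.window_fit <- function(object, ...) {
  long <- object$log |>
    dplyr::select("epoch", "train_loss", "val_loss", "val_mean_auc") |>
    tidyr::pivot_longer(-"epoch", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_epoch,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = sprintf("Training (%s); dashed line = selected checkpoint",
                                  object$model_config$mode))
}

#' Plot an evaluation report
#'
#' Per-class AUC point estimates with bootstrap confidence intervals.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- tidy(object) |> dplyr::filter(!is.na(.data$auc))
  ggplot2::ggplot(d, ggplot2::aes(.data$auc, stats::reorder(.data$class,
                                                            .data$auc))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "AUC", y = NULL,
                  title = sprintf("Per-class AUC, mean %.3f",
                                  attr(object, "mean_auc")))
}

#' Plot a window set as intensity intervals
#'
#' Each window drawn as a horizontal segment from its lower to its upper
#' limit - the standard way to compare initial and learned windows.
#'
#' @param windows A window data frame (level, width); inverted or
#'   degenerate rows (from [extract_learned_windows()]) are dropped with
#'   a message.
#' @param label Optional name for the set (used as the y-axis label
#'   grouping when comparing sets; a `set` column in `windows` is also
#'   honoured).
#' @return A ggplot.
#' @export
plot_windows <- function(windows, label = NULL) {
  d <- tibble::as_tibble(windows)
  if (!"set" %in% names(d)) d$set <- label %||% "windows"
  bad <- (!is.na(d$width) & d$width <= 0) | is.na(d$width)
  if (any(bad)) {
    message(sum(bad), " inverted/degenerate window(s) not drawn")
    d <- d[!bad, ]
  }
  d <- d |>
    dplyr::mutate(lower = .data$level - .data$width / 2,
                  upper = .data$level + .data$width / 2) |>
    dplyr::arrange(.data$level) |>
    dplyr::mutate(idx = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(y = factor(.data$idx), colour = .data$set)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lower, xend = .data$upper,
                                       yend = factor(.data$idx))) +
    ggplot2::geom_point(ggplot2::aes(x = .data$level)) +
    ggplot2::labs(x = "intensity", y = "window",
                  title = "Windows as intensity intervals (dot = level)")
}
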