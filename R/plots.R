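# Plotting helpers (ggplot2).

#' Plot a bilateral pair with its ground-truth boxes
#'
#' @param pair A `bilateral_pair`.
#' @param show_distractors Also outline the bilateral distractors?
#' @returns A ggplot object (two facets: left and right).
#' @export
plot_pair <- function(pair, show_distractors = FALSE) {
  img_df <- function(img, side) {
    tibble::tibble(
      x = rep(seq_len(ncol(img)) - 0.5, each = nrow(img)),
      y = rep(seq_len(nrow(img)) - 0.5, times = ncol(img)),
      value = as.vector(img), side = side)
  }
  box_df <- function(b, side, kind) {
    if (nrow(b) == 0) return(NULL)
    dplyr::mutate(b, side = side, kind = kind)
  }
  d <- dplyr::bind_rows(img_df(pair$left_image, "left"),
                        img_df(pair$right_image, "right"))
  bx <- dplyr::bind_rows(box_df(pair$left_boxes, "left", "lesion"),
                         box_df(pair$right_boxes, "right", "lesion"))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~side) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(bx) && nrow(bx) > 0) {
    p <- p + ggplot2::geom_rect(
      data = bx, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                   ymin = .data$y, ymax = .data$y + .data$h),
      colour = "red", fill = NA, linewidth = 0.4)
  }
  p
}

#' Autoplot method for threshold-sweep tables
#'
#' Reproduces the standard operating-point view: precision, recall, F1 and
#' F2 as functions of T1, with and without the verification stage.
#'
#' @param object A `sweep_table` from [threshold_sweep()].
#' @param ... Unused.
#' @returns A ggplot object faceted by metric.
#' @export
autoplot.sweep_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = c("precision", "recall", "f1", "f2"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$T1, y = .data$value,
                                     colour = .data$filtered)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "T1 (forwarding threshold)", y = NULL,
                  colour = "verified") +
    ggplot2::theme_minimal()
}

#' Autoplot method for fitted models' training traces
#'
#' @param object A `detector_fit` or `scnn_fit`.
#' @param ... Unused.
#' @returns A ggplot object of loss against epoch.
#' @export
autoplot.detector_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.detector_fit
#' @export
autoplot.scnn_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              cols = -dplyr::any_of(c("epoch", "member")),
                              names_to = "series", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
  if ("member" %in% names(object$trace)) {
    p <- p + ggplot2::facet_wrap(~member)
  }
  p
}
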