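# broom-style accessors for fitted objects.

#' Tidy a detector fit
#'
#' @param x A `detector_fit`.
#' @param ... Unused.
#' @returns The per-epoch loss trace as a tibble (`epoch`, `loss`).
#' @export
tidy.detector_fit <- function(x, ...) {
  x$loss_trace
}

#' @rdname tidy.detector_fit
#' @export
glance.detector_fit <- function(x, ...) {
  tibble::tibble(n_images = x$n_images,
                 epochs = nrow(x$loss_trace),
                 initial_loss = x$loss_trace$loss[1],
                 final_loss = tail(x$loss_trace$loss, 1),
                 input_size = x$model$cfg$input_size,
                 head_channels = head_channels(x$model$cfg))
}

#' Tidy a similarity-filter fit
#'
#' @param x An `scnn_fit`.
#' @param ... Unused.
#' @returns The per-epoch trace (`epoch`, `loss`, `val_acc_similar`,
#'   `val_acc_dissimilar`).
#' @export
tidy.scnn_fit <- function(x, ...) {
  x$trace
}

#' @rdname tidy.scnn_fit
#' @export
glance.scnn_fit <- function(x, ...) {
  last <- tail(x$trace, 1)
  tibble::tibble(n_train = x$n_train, n_val = length(x$val_idx),
                 epochs = max(x$trace$epoch),
                 n_members = max(c(1, x$trace$member)),
                 decision_threshold = x$decision_threshold,
                 final_loss = last$loss,
                 val_acc_similar = last$val_acc_similar,
                 val_acc_dissimilar = last$val_acc_dissimilar)
}

#' Tidy a match result
#'
#' @param x A `match_result`.
#' @param ... Unused.
#' @returns One-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `f2`.
#' @export
tidy.match_result <- function(x, ...) {
  pr <- suppressWarnings(precision_recall(x))
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = pr[["precision"]], recall = pr[["recall"]],
                 f1 = fbeta(pr[["precision"]], pr[["recall"]], 1),
                 f2 = fbeta(pr[["precision"]], pr[["recall"]], 2))
}
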