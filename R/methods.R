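# broom-style accessors and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-epoch loss trace of a fit
#' @param x An `mhnet_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @export
tidy.mhnet_fit <- function(x, ...) x$trace

#' One-row summary of a fit
#' @param x An `mhnet_fit`.
#' @param ... Unused.
#' @return Tibble with variant, parameter count, epochs, best epoch, final
#'   losses.
#' @export
glance.mhnet_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(variant = x$config$variant,
                 n_params = tree_n_params(x$params),
                 epochs = nrow(x$trace),
                 best_epoch = x$best_epoch,
                 train_loss = last$train_loss,
                 val_loss = last$val_loss)
}

#' Tidy cross-validation results
#' @param x An `mhnet_cv`.
#' @param ... Unused.
#' @return Per-fold metric tibble.
#' @export
tidy.mhnet_cv <- function(x, ...) x$per_fold

#' Cross-validation summary (mean and sd per metric)
#' @param x An `mhnet_cv`.
#' @param ... Unused.
#' @return Tibble with `metric`, `mean`, `sd`.
#' @export
glance.mhnet_cv <- function(x, ...) x$summary

#' Plot a retained-edge curve
#' @param object A [retained_edge_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.retained_edge_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$gamma, y = .data$retained_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cutoff threshold", y = "fraction of retained edges")
}

#' Plot the training loss trace
#' @param object An `mhnet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mhnet_fit <- function(object, ...) {
  tr <- object$trace
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$train_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss")
  if (any(is.finite(tr$val_loss))) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$val_loss), linetype = 2,
                                na.rm = TRUE)
  }
  p
}

#' @importFrom ggplot2 .data
NULL
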