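#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-barcode tidy summary of a doublet annotation run
#'
#' @param x a `doublet_result` from [run_pipeline()].
#' @param ... unused.
#' @return tibble with columns `barcode`, `doublet_score`, `doublet_call`.
#' @method tidy doublet_result
#' @export
tidy.doublet_result <- function(x, ...) {
  x$scores
}

#' One-row summary of a doublet annotation run
#'
#' @param x a `doublet_result` from [run_pipeline()].
#' @param ... unused.
#' @return one-row tibble: `n_cells`, `nd_hat` (preliminary doublet-count
#'   estimate), `mu`, `sigma` (expected count and its SD), `threshold`,
#'   `n_called`, `vae_epochs`, `runtime_s`.
#' @method glance doublet_result
#' @export
glance.doublet_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$scores),
    nd_hat = x$nd_hat,
    mu = x$mu,
    sigma = x$sigma,
    threshold = if (!is.null(x$call)) x$call$threshold else NA_real_,
    n_called = if (!is.null(x$call)) x$call$n_called else NA_integer_,
    vae_epochs = nrow(x$vae_history),
    runtime_s = x$runtime_s
  )
}

#' Tidy cost curve of a threshold selection
#'
#' @param x a `call_result` from [call_doublets()].
#' @param ... unused.
#' @return tibble of candidate thresholds with `fnr`, `fpr`, `n_called`,
#'   `penalty`, `cost`.
#' @method tidy call_result
#' @export
tidy.call_result <- function(x, ...) {
  x$cost_curve
}

#' Plot the doublet-score distribution of a run
#'
#' Histogram of final doublet scores for input cells, with the selected
#' threshold marked when calls were made.
#'
#' @param object a `doublet_result`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot doublet_result
#' @export
autoplot.doublet_result <- function(object, bins = 50, ...) {
  df <- object$scores
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$doublet_score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::labs(x = "doublet score", y = "cells",
                  title = "Doublet-score distribution")
  if (!is.null(object$call)) {
    p <- p + ggplot2::geom_vline(xintercept = object$call$threshold,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Plot the threshold-selection cost curve
#'
#' Shows FNR, FPR, the expected-count penalty and their sum across
#' candidate thresholds, with the selected threshold marked.
#'
#' @param object a `call_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot call_result
#' @export
autoplot.call_result <- function(object, ...) {
  cc <- object$cost_curve
  long <- tibble::tibble(
    threshold = rep(cc$threshold, 4L),
    term = rep(c("FNR", "FPR", "penalty", "total cost"),
               each = nrow(cc)),
    value = c(cc$fnr, cc$fpr, cc$penalty, cc$cost)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "score threshold", y = "cost term",
                  title = "Doublet-calling cost decomposition")
}

#' Plot VAE training history
#'
#' @param object a trained `vae_model`.
#' @param ... unused.
#' @return a ggplot object of train/validation loss per epoch.
#' @method autoplot vae_model
#' @export
autoplot.vae_model <- function(object, ...) {
  h <- object$history
  if (is.null(h)) dv_stop("model has no training history", "dv_validation_error")
  long <- tibble::tibble(
    epoch = rep(h$epoch, 2L),
    split = rep(c("train", "validation"), each = nrow(h)),
    loss = c(h$train_loss, h$val_loss)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "VAE training history")
}

#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
#' @export
ggplot2::autoplot
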