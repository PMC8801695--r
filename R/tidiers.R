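#' Tidy a trained kernel-conversion model
#'
#' One row per training epoch with its recorded loss.
#'
#' @param x a `kernel_model`.
#' @param ... unused.
#' @return tibble with `epoch`, `loss`, `learning_rate`.
#' @export
tidy.kernel_model <- function(x, ...) {
  e <- seq_along(x$loss_history)
  lr <- if (!is.null(x$train_config)) lr_per_epoch(x$train_config) else NA_real_
  tibble(epoch = e, loss = x$loss_history, learning_rate = lr)
}

#' @rdname tidy.kernel_model
#' @return for `glance`: a one-row tibble with the model id, HU window,
#'   parameter count, epochs, and final loss.
#' @export
glance.kernel_model <- function(x, ...) {
  tibble(
    id = x$id,
    window_lo = x$normalizer$window_lo,
    window_hi = x$normalizer$window_hi,
    n_parameters = n_network_parameters(x$config),
    epochs = length(x$loss_history),
    final_loss = if (length(x$loss_history)) tail_loss(x) else NA_real_
  )
}

#' Tidy a Bland-Altman result
#'
#' @param x a `bland_altman` object.
#' @param ... unused.
#' @return `tidy`: one row per pair (`mean`, `diff`); `glance`: one row
#'   with `bias`, `loa_lo`, `loa_hi`, `sd`, `n`.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble(mean = x$means, diff = x$diffs)
}

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(bias = x$bias, loa_lo = x$loa_lo, loa_hi = x$loa_hi, sd = x$sd,
         n = x$n)
}
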