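#' Box-style plot of per-band error summaries
#'
#' Mirrors the usual presentation of conversion error against phantom
#' inter-scan variability: one crossbar per method per band built from the
#' summary quartiles (the summaries carry quartiles, not raw voxels, so
#' whiskers are omitted).
#'
#' @param summaries a band-summary tibble with a `method` column, e.g.
#'   `run_validation(...)$band_errors`, optionally row-bound with the
#'   phantom summary tagged as its own method.
#' @return a ggplot object.
#' @export
plot_band_errors <- function(summaries) {
  df <- dplyr::filter(summaries, !.data$empty, .data$band != "all")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, fill = .data$method)) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      position = ggplot2::position_dodge(width = 0.8), width = 0.7,
      linewidth = 0.3
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "HU band (reference value)",
                  y = "CT-value difference vs reference (HU)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bland-Altman plot
#'
#' Mean of the paired measurements on the x-axis, their difference on the
#' y-axis, with the bias (solid) and 95% limits of agreement (dashed).
#'
#' @param object a `bland_altman` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lo, object$loa_hi),
                        linetype = 2) +
    ggplot2::labs(x = "Mean of methods", y = "Difference (test - reference)") +
    ggplot2::theme_minimal()
}

#' Training-loss curve of a kernel-conversion model
#'
#' @param object a `kernel_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kernel_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Epoch", y = "Training loss (normalised units)",
                  title = sprintf("Model '%s'", object$id)) +
    ggplot2::theme_minimal()
}

#' Middle axial slice of a volume as a ggplot image
#'
#' Quick visual check of volumes and conversions with a standard CT
#' grey window.
#'
#' @param object a [ct_volume()].
#' @param slice slice index (default: middle slice).
#' @param window display window `c(lo, hi)` in HU.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ct_volume <- function(object, slice = NULL,
                               window = c(-1000, 300), ...) {
  d <- dim(object$voxels)
  slice <- slice %||% ((d[1] + 1) %/% 2)
  sl <- object$voxels[slice, , ]
  df <- expand.grid(row = seq_len(d[2]), col = seq_len(d[3]))
  df$hu <- pmin(pmax(as.vector(sl), window[1]), window[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = window) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (slice %d)", object$kernel_label, slice),
                  fill = "HU") +
    ggplot2::theme_void()
}
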