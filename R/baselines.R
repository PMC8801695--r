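#' Gaussian-filter conversion baseline
#'
#' Classical sharp-to-soft conversion by per-slice 2-D Gaussian smoothing.
#' `sigma_mm` is expressed in millimetres and converted to voxels through
#' the in-plane spacing. Outside-FOV voxels are excluded from the filter by
#' mask-normalised convolution and restored to the padding value afterwards.
#'
#' @param vol a [ct_volume()].
#' @param sigma_mm Gaussian sigma in mm (> 0).
#' @return a filtered [ct_volume()].
#' @export
gaussian_convert <- function(vol, sigma_mm) {
  assert_ct_volume(vol)
  if (!is.finite(sigma_mm) || sigma_mm <= 0) {
    stop_param("`sigma_mm` must be a positive number.")
  }
  sig_r <- sigma_mm / vol$spacing_mm[2]
  sig_c <- sigma_mm / vol$spacing_mm[3]
  valid <- validity_mask(vol)
  out <- vol
  for (s in seq_len(dim(vol$voxels)[1])) {
    sl <- vol$voxels[s, , ]
    v <- valid[s, , ] * 1.0
    num <- gaussian_blur_cpp(sl * v, sig_r, sig_c)
    den <- gaussian_blur_cpp(v, sig_r, sig_c)
    flt <- ifelse(den > 0, num / pmax(den, .Machine$double.eps), sl)
    flt[v == 0] <- vol$padding_value
    out$voxels[s, , ] <- flt
  }
  out$kernel_label <- sprintf("gaussian(%.3g mm)", sigma_mm)
  out
}

#' Median-filter conversion baseline
#'
#' Per-slice square-window median filter of radius `radius_vox` voxels
#' (window side `2 * radius_vox + 1`). Outside-FOV voxels are restored to
#' the padding value after filtering.
#'
#' @param vol a [ct_volume()].
#' @param radius_vox window radius in voxels (integer >= 1).
#' @return a filtered [ct_volume()].
#' @export
median_convert <- function(vol, radius_vox = 1) {
  assert_ct_volume(vol)
  radius_vox <- as.integer(radius_vox)
  if (radius_vox < 1) stop_param("`radius_vox` must be >= 1.")
  valid <- validity_mask(vol)
  out <- vol
  for (s in seq_len(dim(vol$voxels)[1])) {
    flt <- median_filter_cpp(vol$voxels[s, , ], radius_vox)
    flt[!valid[s, , ]] <- vol$padding_value
    out$voxels[s, , ] <- flt
  }
  out$kernel_label <- sprintf("median(r=%d)", radius_vox)
  out
}

#' Calibrate a baseline filter on matched slice pairs
#'
#' The published comparison filters come without stated parameters, so the
#' baseline parameter is chosen by exhaustive grid search: the value
#' minimising the mean squared error between the filtered sharp slices and
#' the soft slices over the training pairs. Ties break to the smallest
#' parameter. Deterministic.
#'
#' @param pairs a [slice_pair_set()].
#' @param kind `"gaussian"` (grid of sigma, mm) or `"median"` (grid of
#'   integer radii).
#' @param grid candidate parameters; defaults to sigma 0.5..3.0 mm
#'   (step 0.25) for Gaussian and radii 1..3 for median.
#' @param spacing_mm in-plane spacing `(dy, dx)` of the slices in mm.
#' @return list with `parameter` (best value), `mse` (its mean squared
#'   error), and the full `grid_mse` tibble.
#' @export
calibrate_filter <- function(pairs, kind = c("gaussian", "median"),
                             grid = NULL, spacing_mm = c(1, 1)) {
  kind <- match.arg(kind)
  if (!inherits(pairs, "slice_pair_set") || length(pairs) < 1) {
    stop_data("non-empty slice pairs are required for calibration.")
  }
  if (is.null(grid)) {
    grid <- if (kind == "gaussian") seq(0.5, 3.0, by = 0.25) else 1:3
  }
  if (!length(grid)) stop_data("parameter grid must be non-empty.")
  grid <- sort(unique(grid))
  valid <- pairs$sharp > pairs$padding_value & pairs$soft > pairs$padding_value
  n <- length(pairs)
  mse <- vapply(grid, function(p) {
    se <- 0
    cnt <- 0
    for (i in seq_len(n)) {
      sl <- pairs$sharp[i, , ]
      flt <- if (kind == "gaussian") {
        gaussian_blur_cpp(sl, p / spacing_mm[1], p / spacing_mm[2])
      } else {
        median_filter_cpp(sl, as.integer(p))
      }
      v <- valid[i, , ]
      d <- (flt - pairs$soft[i, , ])[v]
      se <- se + sum(d^2)
      cnt <- cnt + sum(v)
    }
    se / cnt
  }, 0)
  best <- which.min(mse) # first minimum = smallest parameter on ties
  list(parameter = grid[best], mse = mse[best],
       grid_mse = tibble(parameter = grid, mse = mse))
}
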