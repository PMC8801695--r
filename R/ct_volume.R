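#' CT volume in Hounsfield units
#'
#' The universal container of the package: a 3-D grid of Hounsfield-unit (HU)
#' values together with its physical voxel spacing, a free-text reconstruction
#' kernel label, and the padding value that marks voxels outside the scanner
#' field of view.
#'
#' Axes follow the `(slice, row, col)` convention: `dim(voxels)` is
#' `(n_slice, n_row, n_col)` and `spacing_mm` is `(dz, dy, dx)`. Values are
#' held as R doubles: converted images are real-valued, so integer storage
#' types from DICOM/NIfTI sources are promoted on read.
#'
#' @param voxels 3-D numeric array of HU values, `(slice, row, col)`.
#' @param spacing_mm length-3 positive numeric, `(dz, dy, dx)` in mm.
#' @param kernel_label free-text reconstruction kernel tag (e.g. `"FC51"`,
#'   `"FC13"`, `"converted(full)"`).
#' @param padding_value HU value marking outside-FOV voxels (default -2048).
#'   Voxels at or below this value are excluded from all downstream
#'   statistics via [validity_mask()].
#' @param origin_mm axial (z) position of the first slice in mm; slice `i`
#'   sits at `origin_mm + (i - 1) * dz`. Used for slice-location matching.
#' @return A `ct_volume` object.
#' @seealso [read_volume()], [write_volume()], [truncate_hu()], [pair_slices()]
#' @export
#' @examples
#' vol <- ct_volume(array(-870, dim = c(4, 8, 8)), spacing_mm = c(1, 0.7, 0.7))
#' dim(vol$voxels)
ct_volume <- function(voxels, spacing_mm = c(1, 1, 1), kernel_label = "unknown",
                      padding_value = -2048, origin_mm = 0) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_shape("`voxels` must be a 3-D array (slice, row, col).")
  }
  if (any(dim(voxels) < 1L)) stop_shape("all voxel array dimensions must be >= 1.")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0)) {
    stop_param("`spacing_mm` must be three positive finite numbers (dz, dy, dx).")
  }
  storage.mode(voxels) <- "double"
  if (any(!is.finite(voxels))) {
    stop_data("voxel values must all be finite (no NA/NaN/Inf).")
  }
  structure(
    list(
      voxels = voxels,
      spacing_mm = as.numeric(spacing_mm),
      kernel_label = as.character(kernel_label)[1],
      padding_value = as.numeric(padding_value)[1],
      origin_mm = as.numeric(origin_mm)[1]
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d x %d (slice x row x col), spacing %.3g/%.3g/%.3g mm, kernel '%s'\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3], x$kernel_label
  ))
  v <- x$voxels[validity_mask(x)]
  if (length(v)) {
    cat(sprintf("  HU range [%.1f, %.1f] over %d in-FOV voxels\n",
                min(v), max(v), length(v)))
  }
  invisible(x)
}

is_ct_volume <- function(x) inherits(x, "ct_volume")

assert_ct_volume <- function(x, arg = "vol") {
  if (!is_ct_volume(x)) stop_param(sprintf("`%s` must be a ct_volume object.", arg))
  invisible(x)
}

#' Validity mask of in-FOV voxels
#'
#' Logical array marking voxels strictly above the volume's padding value.
#' All statistics in the package (training loss, band errors, calibration)
#' are restricted to valid voxels.
#'
#' @param vol a [ct_volume()].
#' @return logical array of the same shape as `vol$voxels`.
#' @export
validity_mask <- function(vol) {
  assert_ct_volume(vol)
  vol$voxels > vol$padding_value
}

#' Axial slice positions of a volume
#'
#' @param vol a [ct_volume()].
#' @return numeric vector of z positions in mm, one per slice.
#' @export
slice_locations <- function(vol) {
  assert_ct_volume(vol)
  vol$origin_mm + (seq_len(dim(vol$voxels)[1]) - 1) * vol$spacing_mm[1]
}

#' Labelled region mask aligned to a CT volume
#'
#' @param labels 3-D integer array, same shape as the companion volume;
#'   0 is background, positive integers are regions.
#' @param region_names named character vector mapping label (as name) to a
#'   region name, e.g. `c("1" = "lung", "2" = "muscle")`. Optional.
#' @return A `region_mask` object.
#' @export
region_mask <- function(labels, region_names = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop_shape("`labels` must be a 3-D array.")
  }
  if (any(labels < 0)) stop_data("mask labels must be non-negative.")
  if (any(labels != round(labels))) stop_data("mask labels must be integers.")
  storage.mode(labels) <- "integer"
  if (is.null(region_names)) {
    lv <- sort(unique(labels[labels > 0L]))
    region_names <- setNames(paste0("region_", lv), as.character(lv))
  }
  structure(list(labels = labels, region_names = region_names), class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<region_mask> %d x %d x %d; regions: %s\n", d[1], d[2], d[3],
              paste(sprintf("%s=%s", names(x$region_names), x$region_names),
                    collapse = ", ")))
  invisible(x)
}

is_region_mask <- function(x) inherits(x, "region_mask")

# Coerce a region_mask / logical array / numeric 3-D array to a logical
# inclusion array; `label` restricts a labelled mask to one region.
as_binary_mask <- function(mask, label = NULL) {
  if (is_region_mask(mask)) {
    if (is.null(label)) return(mask$labels > 0L)
    if (is.character(label)) {
      hit <- names(mask$region_names)[mask$region_names %in% label]
      if (!length(hit)) {
        stop_data(sprintf("no region named '%s' in mask.",
                          paste(label, collapse = "', '")))
      }
      label <- as.integer(hit)
    }
    return(array(mask$labels %in% as.integer(label), dim = dim(mask$labels)))
  }
  if (is.logical(mask)) return(mask)
  if (is.array(mask) && length(dim(mask)) == 3L) return(mask > 0)
  stop_param("mask must be a region_mask, a logical array, or a 0/1 array.")
}

#' Clamp a volume to a Hounsfield-unit window
#'
#' Truncates every voxel to `[lo, hi]`, the operation used to build the
#' partial (region-wise) training data: mid-range models are trained on
#' images clamped to -300..300 HU. Metadata (spacing, padding, origin) is
#' preserved; the kernel label is annotated.
#'
#' @param vol a [ct_volume()].
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return a `ct_volume` with voxels clamped to `[lo, hi]`.
#' @export
#' @examples
#' v <- ct_volume(array(c(-1000, 0, 500), dim = c(3, 1, 1)))
#' truncate_hu(v, -300, 300)$voxels[, 1, 1]
truncate_hu <- function(vol, lo, hi) {
  assert_ct_volume(vol)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop_param("`lo` must be strictly less than `hi`.")
  }
  out <- vol
  out$voxels <- pmin(pmax(vol$voxels, lo), hi)
  dim(out$voxels) <- dim(vol$voxels)
  out$kernel_label <- sprintf("%s[%g,%g]", vol$kernel_label, lo, hi)
  out
}

#' Matched sharp/soft slice pairs
#'
#' Container for anatomically matched 2-D slice pairs from a sharp-kernel
#' and a soft-kernel reconstruction of the same scan: the unit of network
#' training and evaluation. Constructed by [pair_slices()].
#'
#' @param sharp,soft 3-D arrays `(pair, row, col)` with one matched slice
#'   per pair.
#' @param locations_mm strictly increasing axial positions of the pairs.
#' @param source_id free-text provenance tag.
#' @param padding_value HU padding value inherited from the source volumes.
#' @return A `slice_pair_set` object.
#' @export
slice_pair_set <- function(sharp, soft, locations_mm, source_id = "",
                           padding_value = -2048) {
  if (!identical(dim(sharp), dim(soft))) {
    stop_shape("sharp and soft slice stacks must have identical shapes.")
  }
  if (length(dim(sharp)) != 3L) stop_shape("slice stacks must be 3-D (pair, row, col).")
  n <- dim(sharp)[1]
  if (length(locations_mm) != n) stop_shape("one location per pair is required.")
  if (n > 1 && any(diff(locations_mm) <= 0)) {
    stop_data("pair locations must be strictly increasing.")
  }
  storage.mode(sharp) <- "double"
  storage.mode(soft) <- "double"
  structure(
    list(sharp = sharp, soft = soft, locations_mm = as.numeric(locations_mm),
         source_id = as.character(source_id)[1],
         padding_value = as.numeric(padding_value)[1]),
    class = "slice_pair_set"
  )
}

#' @export
print.slice_pair_set <- function(x, ...) {
  d <- dim(x$sharp)
  cat(sprintf("<slice_pair_set> %d pairs of %d x %d slices (source '%s')\n",
              d[1], d[2], d[3], x$source_id))
  invisible(x)
}

#' @export
length.slice_pair_set <- function(x) dim(x$sharp)[1]

# Concatenate several slice_pair_sets (used to pool patients for training).
bind_pairs <- function(sets) {
  stopifnot(length(sets) >= 1)
  sharp <- do.call(abind_slices, lapply(sets, `[[`, "sharp"))
  soft <- do.call(abind_slices, lapply(sets, `[[`, "soft"))
  # locations lose anatomical meaning across subjects; keep a running index
  slice_pair_set(sharp, soft, seq_len(dim(sharp)[1]),
                 source_id = paste(vapply(sets, `[[`, "", "source_id"),
                                   collapse = "+"),
                 padding_value = sets[[1]]$padding_value)
}

abind_slices <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[2:3]
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, dim = c(n, d))
  at <- 0L
  for (p in parts) {
    np <- dim(p)[1]
    out[at + seq_len(np), , ] <- p
    at <- at + np
  }
  out
}

#' Match sharp-kernel slices to soft-kernel slice locations
#'
#' Clinical reconstructions pair a 0.5 mm sharp-kernel stack with a 1.0 mm
#' soft-kernel stack of the same scan, so every other sharp slice falls at a
#' soft slice location. For each soft slice this selects the sharp slice
#' whose physical axial position is nearest (nearest-neighbour on positions,
#' not index arithmetic, so half-slice origin offsets are tolerated; ties go
#' to the lower index).
#'
#' @param sharp a [ct_volume()] with slice spacing approximately half of
#'   `soft`'s (ratio within 5%).
#' @param soft a [ct_volume()]; defines the output pair locations.
#' @return a [slice_pair_set()] with one pair per soft slice.
#' @export
pair_slices <- function(sharp, soft) {
  assert_ct_volume(sharp, "sharp")
  assert_ct_volume(soft, "soft")
  ds <- dim(sharp$voxels)
  dv <- dim(soft$voxels)
  if (!identical(ds[2:3], dv[2:3])) {
    stop_shape("sharp and soft volumes must share in-plane shape.")
  }
  ratio <- sharp$spacing_mm[1] / soft$spacing_mm[1]
  if (abs(ratio / 0.5 - 1) > 0.05) {
    stop_data(sprintf(
      "sharp slice spacing must be half of soft spacing (ratio %.3f, expected 0.5 within 5%%).",
      ratio
    ))
  }
  loc_sharp <- slice_locations(sharp)
  loc_soft <- slice_locations(soft)
  idx <- vapply(loc_soft, function(z) which.min(abs(loc_sharp - z)), 0L)
  n <- dv[1]
  sharp_sel <- array(0, dim = c(n, ds[2], ds[3]))
  soft_sel <- array(0, dim = c(n, ds[2], ds[3]))
  for (i in seq_len(n)) {
    sharp_sel[i, , ] <- sharp$voxels[idx[i], , ]
    soft_sel[i, , ] <- soft$voxels[i, , ]
  }
  slice_pair_set(sharp_sel, soft_sel, loc_soft,
                 source_id = sprintf("%s|%s", sharp$kernel_label, soft$kernel_label),
                 padding_value = max(sharp$padding_value, soft$padding_value))
}
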