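#' Clinical quantification indices
#'
#' Standard density-threshold CT indices used to validate kernel
#' conversions: emphysema low-attenuation volume percentage (LAV%, lung
#' voxels below -950 HU), intramuscular adipose tissue percentage (IMAT%,
#' muscle voxels below -30 HU), and coronary artery calcium volume (CAC,
#' coronary-ROI voxels above 130 HU times the per-voxel volume). All
#' threshold comparisons are strict (`<`, `>`): boundary values are
#' excluded. Each function returns a one-row tibble with the index name,
#' value, threshold, and voxel counts.
#'
#' @param vol a [ct_volume()].
#' @param lung_mask,muscle_mask,coronary_mask a [region_mask()], logical
#'   array, or 0/1 array selecting the region; must be non-empty.
#' @param mask_name provenance tag recorded in the result.
#' @name quantify
NULL

quant_row <- function(index_name, value, threshold, mask_name, n_region, n_pos) {
  tibble(index_name = index_name, value = value, threshold_HU = threshold,
         mask_name = mask_name, n_voxels_region = n_region,
         n_voxels_positive = n_pos)
}

check_region <- function(vol, mask, what) {
  assert_ct_volume(vol)
  m <- as_binary_mask(mask)
  if (!identical(dim(m), dim(vol$voxels))) {
    stop_shape(sprintf("%s mask shape must match the volume.", what))
  }
  if (!any(m)) stop_data(sprintf("%s mask is empty.", what))
  m
}

#' @rdname quantify
#' @export
#' @examples
#' v <- ct_volume(array(c(-960, -900, -900, -900), dim = c(1, 2, 2)))
#' m <- array(TRUE, dim = c(1, 2, 2))
#' lav_percent(v, m)$value # 25
lav_percent <- function(vol, lung_mask, mask_name = "lung") {
  m <- check_region(vol, lung_mask, "lung")
  n <- sum(m)
  pos <- sum(vol$voxels[m] < -950)
  quant_row("LAV%", 100 * pos / n, -950, mask_name, n, pos)
}

#' Binary mask of low-attenuation (emphysematous) lung voxels
#'
#' Lung voxels with HU strictly below -950.
#'
#' @inheritParams quantify
#' @return a [region_mask()] with label 1 = low-attenuation voxel.
#' @export
low_attenuation_mask <- function(vol, lung_mask) {
  m <- check_region(vol, lung_mask, "lung")
  lab <- array(0L, dim = dim(vol$voxels))
  lab[m & vol$voxels < -950] <- 1L
  region_mask(lab, c("1" = "low_attenuation"))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks give 1 by convention.
#'
#' @param a,b [region_mask()] objects or logical/0-1 arrays of one shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  ma <- as_binary_mask(a)
  mb <- as_binary_mask(b)
  if (!identical(dim(ma), dim(mb))) stop_shape("masks must share one shape.")
  na <- sum(ma)
  nb <- sum(mb)
  if (na + nb == 0) return(1)
  2 * sum(ma & mb) / (na + nb)
}

#' @rdname quantify
#' @export
imat_percent <- function(vol, muscle_mask, mask_name = "pectoralis") {
  m <- check_region(vol, muscle_mask, "muscle")
  n <- sum(m)
  pos <- sum(vol$voxels[m] < -30)
  quant_row("IMAT%", 100 * pos / n, -30, mask_name, n, pos)
}

#' @rdname quantify
#' @export
cac_volume <- function(vol, coronary_mask, mask_name = "coronary") {
  m <- check_region(vol, coronary_mask, "coronary")
  n <- sum(m)
  pos <- sum(vol$voxels[m] > 130)
  vox_mm3 <- prod(vol$spacing_mm)
  quant_row("CAC_volume_mm3", pos * vox_mm3, 130, mask_name, n, pos)
}

#' Toy lung segmentation for synthetic data (non-validated)
#'
#' Convenience only: thresholds voxels below -200 HU, discards air
#' components touching the in-plane border (outside-body air), and fills
#' holes per slice. Intended solely for simulator phantoms; it is NOT a
#' validated clinical lung segmentation, and real-data analyses should
#' supply their own masks. Requires the EBImage package.
#'
#' @param vol a [ct_volume()].
#' @return a [region_mask()] with label 1 = lung.
#' @export
segment_lungs_simple <- function(vol) {
  assert_ct_volume(vol)
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop_param("segment_lungs_simple needs the EBImage package.")
  }
  warn("segment_lungs_simple is a non-validated convenience for synthetic data only.")
  d <- dim(vol$voxels)
  lab <- array(0L, dim = d)
  for (s in seq_len(d[1])) {
    b <- vol$voxels[s, , ] < -200 & validity_mask(vol)[s, , ]
    cc <- EBImage::bwlabel(b)
    border <- unique(c(cc[1, ], cc[d[2], ], cc[, 1], cc[, d[3]]))
    border <- border[border > 0]
    keep <- b & !(cc %in% border)
    keep <- EBImage::fillHull(matrix(as.numeric(keep), d[2], d[3])) > 0
    lab[s, , ][keep] <- 1L
  }
  region_mask(lab, c("1" = "lung"))
}
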