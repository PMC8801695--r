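#' Hounsfield-unit analysis bands
#'
#' The standard error-profiling bands: -1000..-600 HU (mainly lung
#' parenchyma), -600..-200, -200..200 (vessel, muscle, adipose tissue),
#' 200..600 (calcification, bone mineral), 600..1000, plus the broad
#' -1000..1000 band. Intervals are half-open `[lo, hi)`.
#'
#' @return tibble with columns `name`, `lo`, `hi`.
#' @export
default_hu_bands <- function() {
  tibble(
    name = c("[-1000,-600)", "[-600,-200)", "[-200,200)", "[200,600)",
             "[600,1000)", "broad[-1000,1000)"),
    lo = c(-1000, -600, -200, 200, 600, -1000),
    hi = c(-600, -200, 200, 600, 1000, 1000)
  )
}

check_bands <- function(bands) {
  if (!is.data.frame(bands) || !all(c("name", "lo", "hi") %in% names(bands))) {
    stop_param("`bands` must be a data frame with name, lo, hi columns.")
  }
  if (any(bands$lo >= bands$hi)) stop_param("each band needs lo < hi.")
  bands
}

summarize_band <- function(name, lo, hi, diffs) {
  n <- length(diffs)
  if (n == 0) {
    return(tibble(band = name, lo = lo, hi = hi, n = 0L, median = NA_real_,
                  q1 = NA_real_, q3 = NA_real_, mean = NA_real_,
                  sd = NA_real_, empty = TRUE))
  }
  q <- unname(quantile(diffs, c(0.25, 0.5, 0.75), type = 7))
  tibble(band = name, lo = lo, hi = hi, n = n, median = q[2], q1 = q[1],
         q3 = q[3], mean = mean(diffs),
         sd = if (n > 1) sd(diffs) else 0, empty = FALSE)
}

#' Per-band CT-value differences between a test and a reference volume
#'
#' Voxelwise differences `test - ref` over in-FOV voxels, summarised per
#' HU band. Band membership is decided by the *reference* voxel value with
#' half-open intervals `[lo, hi)`, so band composition is identical for
#' every method compared against the same reference. A band with no member
#' voxels is flagged `empty`, not an error.
#'
#' @param test,ref [ct_volume()] objects of one shape.
#' @param bands band table as from [default_hu_bands()].
#' @return tibble with one row per band: `band, lo, hi, n, median, q1, q3,
#'   mean, sd, empty`.
#' @export
band_errors <- function(test, ref, bands = default_hu_bands()) {
  assert_ct_volume(test, "test")
  assert_ct_volume(ref, "ref")
  if (!identical(dim(test$voxels), dim(ref$voxels))) {
    stop_shape("test and reference volumes must share one shape.")
  }
  bands <- check_bands(bands)
  valid <- validity_mask(test) & validity_mask(ref)
  rv <- ref$voxels[valid]
  dv <- test$voxels[valid] - rv
  purrr::pmap_dfr(bands, function(name, lo, hi) {
    summarize_band(name, lo, hi, dv[rv >= lo & rv < hi])
  })
}

#' Inter-scan variability of repeated phantom scans
#'
#' The yardstick for acceptable conversion error: CT values of `n`
#' repeated scans of a fixed phantom are averaged voxelwise, and each
#' scan's differences from that average are pooled over all scans and
#' summarised per HU band (band membership by the mean volume). For any
#' scan set the pooled mean difference is 0 up to float error, and with
#' white noise of sd sigma the pooled sd approaches
#' `sigma * sqrt((n-1)/n)`.
#'
#' @param scans list of >= 2 [ct_volume()] objects of one shape.
#' @param bands band table as from [default_hu_bands()].
#' @return tibble as in [band_errors()], plus an `"all"` row pooling every
#'   valid voxel regardless of band.
#' @export
interscan_variability <- function(scans, bands = default_hu_bands()) {
  if (!is.list(scans) || length(scans) < 2) {
    stop_param("at least two scans are required.")
  }
  lapply(scans, assert_ct_volume)
  d <- dim(scans[[1]]$voxels)
  for (s in scans) {
    if (!identical(dim(s$voxels), d)) stop_shape("scans must share one shape.")
  }
  bands <- check_bands(bands)
  mean_vol <- Reduce(`+`, lapply(scans, `[[`, "voxels")) / length(scans)
  valid <- Reduce(`&`, lapply(scans, validity_mask))
  mv <- mean_vol[valid]
  diffs <- lapply(scans, function(s) s$voxels[valid] - mv)
  pooled <- unlist(diffs, use.names = FALSE)
  ref_rep <- rep(mv, length(scans))
  out <- purrr::pmap_dfr(bands, function(name, lo, hi) {
    summarize_band(name, lo, hi, pooled[ref_rep >= lo & ref_rep < hi])
  })
  dplyr::bind_rows(out, summarize_band("all", -Inf, Inf, pooled))
}

#' Compare conversion errors to phantom inter-scan variability
#'
#' Operationalises the visual comparison of error distributions: per band,
#' the conversion's |median| difference is compared to the phantom IQR, and
#' the IQR ratio (conversion / phantom) to a configurable factor. The
#' verdict is `"acceptable"` when |median| <= phantom IQR and the IQR
#' ratio <= `factor`.
#'
#' @param conv,phantom band summary tibbles from [band_errors()] /
#'   [interscan_variability()] with matching band lists.
#' @param factor maximum acceptable IQR ratio (default 1.5).
#' @return tibble with per-band `abs_median`, `phantom_iqr`, `iqr_ratio`,
#'   and logical `acceptable`.
#' @export
compare_to_phantom <- function(conv, phantom, factor = 1.5) {
  if (!setequal(conv$band, phantom$band)) {
    stop_param("conversion and phantom summaries must cover matching bands.")
  }
  shared <- intersect(conv$band, phantom$band)
  cv <- conv[match(shared, conv$band), ]
  ph <- phantom[match(shared, phantom$band), ]
  iqr_c <- cv$q3 - cv$q1
  iqr_p <- ph$q3 - ph$q1
  ratio <- iqr_c / iqr_p
  tibble(
    band = shared,
    abs_median = abs(cv$median),
    phantom_iqr = iqr_p,
    iqr_ratio = ratio,
    acceptable = abs(cv$median) <= iqr_p & ratio <= factor
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences `a - b` of paired measurements: bias is their mean and the
#' 95% limits of agreement are `bias +/- 1.96 * sd` (sample sd, n - 1).
#'
#' @param a test-method values; `b` reference values (equal length >= 2).
#' @param b reference values.
#' @return a `bland_altman` object with `bias`, `loa_lo`, `loa_hi`, `n`,
#'   and the per-pair `means`/`diffs` for plotting.
#' @export
#' @examples
#' ba <- bland_altman(c(10, 12, 14), c(9, 11, 15))
#' ba$bias
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_data("`a` and `b` must have equal length.")
  if (length(a) < 2) stop_data("Bland-Altman needs at least two pairs.")
  diffs <- a - b
  bias <- mean(diffs)
  s <- sd(diffs)
  structure(
    list(bias = bias, loa_lo = bias - 1.96 * s, loa_hi = bias + 1.96 * s,
         sd = s, n = length(a), means = (a + b) / 2, diffs = diffs),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d, bias %.4g (95%% LoA %.4g to %.4g)\n",
              x$n, x$bias, x$loa_lo, x$loa_hi))
  invisible(x)
}

#' Paired t-tests against a reference with Bonferroni correction
#'
#' Runs a paired t-test of the reference scores against each competitor and
#' multiplies each raw p-value by `m` (capped at 1). A zero-variance
#' difference vector is a degenerate test and raises an error rather than
#' silently reporting 0.
#'
#' @param reference_scores numeric vector (length >= 3).
#' @param competitor_scores list of numeric vectors, each paired with the
#'   reference.
#' @param m number of comparisons for the correction; must be at least the
#'   number of competitors (defaults to that number).
#' @param alternative passed to [stats::t.test()] (`"two.sided"` default).
#' @return tibble with `comparison`, `statistic`, `df`, `p_raw`,
#'   `p_adjusted`.
#' @export
paired_t_bonferroni <- function(reference_scores, competitor_scores,
                                m = length(competitor_scores),
                                alternative = "two.sided") {
  if (!is.list(competitor_scores)) competitor_scores <- list(competitor_scores)
  if (m < length(competitor_scores)) {
    stop_param("`m` must be at least the number of comparisons performed.")
  }
  nm <- names(competitor_scores) %||% paste0("competitor_", seq_along(competitor_scores))
  purrr::map2_dfr(competitor_scores, nm, function(comp, label) {
    if (length(comp) != length(reference_scores) || length(comp) < 3) {
      stop_data("each comparison needs equal-length paired samples of >= 3.")
    }
    d <- reference_scores - comp
    if (sd(d) == 0) {
      stop_data(sprintf(
        "degenerate paired t-test for '%s': zero-variance difference vector.",
        label
      ))
    }
    tt <- t.test(reference_scores, comp, paired = TRUE,
                 alternative = alternative)
    tibble(comparison = label, statistic = unname(tt$statistic),
           df = unname(tt$parameter), p_raw = tt$p.value,
           p_adjusted = min(1, m * tt$p.value))
  })
}
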