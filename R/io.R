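#' Read a CT volume from NIfTI or a DICOM series
#'
#' NIfTI files are read through RNifti. DICOM series are read by a minimal
#' built-in parser for uncompressed little-endian (explicit or implicit VR)
#' single-frame axial series: slices are ordered by their physical z
#' position, the DICOM rescale `HU = slope * stored + intercept` is applied,
#' and spacing is populated from the headers. Compressed transfer syntaxes,
#' multi-frame enhanced DICOM, and non-axial reformats are not supported.
#'
#' @param path a NIfTI file or a directory containing one DICOM series.
#' @param format `"auto"` (directory implies DICOM), `"nifti"`, or
#'   `"dicom_series"`.
#' @param padding_value HU padding value to record on the volume.
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series"),
                        padding_value = -2048) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("path does not exist: %s", path))
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  if (format == "nifti") read_volume_nifti(path, padding_value)
  else read_volume_dicom(path, padding_value)
}

read_volume_nifti <- function(path, padding_value) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) {
    stop_format(sprintf("expected a 3-D NIfTI volume, got %d dims: %s",
                        length(dim(arr)), path))
  }
  pd <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  origin <- if (is.matrix(xf) && all(dim(xf) == c(4, 4))) xf[3, 4] else 0
  vox <- aperm(arr, c(3, 2, 1)) # (x, y, z) -> (slice, row, col)
  attributes(vox) <- list(dim = dim(vox))
  ct_volume(vox, spacing_mm = c(pd[3], pd[2], pd[1]),
            kernel_label = "unknown", padding_value = padding_value,
            origin_mm = origin)
}

#' Write a CT volume or region mask to NIfTI
#'
#' Volumes are written as double precision so that [read_volume()]
#' round-trips voxels bit-exactly; masks are written as 32-bit integers.
#'
#' @param vol a [ct_volume()] or [region_mask()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @param spacing_mm spacing for masks (masks carry no spacing of their own).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, spacing_mm = c(1, 1, 1)) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_format(sprintf("parent directory does not exist: %s", dir))
  if (is_region_mask(vol)) {
    arr <- aperm(vol$labels, c(3, 2, 1))
    attributes(arr) <- list(dim = dim(arr))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(spacing_mm)
    RNifti::writeNifti(img, path, datatype = "int32")
    return(invisible(path))
  }
  assert_ct_volume(vol)
  if (any(!is.finite(vol$voxels))) stop_data("refusing to write non-finite voxels.")
  arr <- aperm(vol$voxels, c(3, 2, 1))
  attributes(arr) <- list(dim = dim(arr))
  img <- RNifti::asNifti(arr)
  sp <- rev(vol$spacing_mm) # (dx, dy, dz)
  RNifti::pixdim(img) <- sp
  xf <- diag(c(sp, 1))
  xf[3, 4] <- vol$origin_mm
  RNifti::qform(img) <- structure(xf, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read an integer-label region mask from NIfTI
#'
#' @param path NIfTI file with integer labels (0 background).
#' @param region_names optional named character vector of label names.
#' @return a [region_mask()].
#' @export
read_mask <- function(path, region_names = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop_format("expected a 3-D NIfTI mask.")
  lab <- aperm(arr, c(3, 2, 1))
  attributes(lab) <- list(dim = dim(lab))
  if (any(abs(lab - round(lab)) > 1e-6)) {
    stop_format("mask file contains non-integer labels.")
  }
  region_mask(array(as.integer(round(lab)), dim = dim(lab)), region_names)
}

## ---- minimal DICOM series reader -------------------------------------------

dcm_u16 <- function(raw, i) {
  as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
}

dcm_u32 <- function(raw, i) {
  as.numeric(raw[i]) + 256 * as.numeric(raw[i + 1L]) +
    65536 * as.numeric(raw[i + 2L]) + 16777216 * as.numeric(raw[i + 3L])
}

DCM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one DICOM file, returning the handful of tags the reader needs.
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  n <- length(raw)
  pos <- 1L
  if (n >= 132L && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  explicit <- TRUE
  ts <- NULL
  out <- list()
  while (pos + 7L <= n) {
    group <- dcm_u16(raw, pos)
    elem <- dcm_u16(raw, pos + 2L)
    meta <- group == 2L
    use_explicit <- meta || explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% DCM_LONG_VRS) {
        len <- dcm_u32(raw, pos + 8L)
        dstart <- pos + 12L
      } else if (grepl("^[A-Z]{2}$", vr)) {
        len <- dcm_u16(raw, pos + 6L)
        dstart <- pos + 8L
      } else {
        # no plausible VR: fall back to implicit encoding for this element
        vr <- "UN"
        len <- dcm_u32(raw, pos + 4L)
        dstart <- pos + 8L
      }
    } else {
      vr <- "UN"
      len <- dcm_u32(raw, pos + 4L)
      dstart <- pos + 8L
    }
    if (len == 4294967295) {
      stop_format(sprintf("undefined-length DICOM elements are not supported: %s", path))
    }
    dend <- dstart + len - 1L
    if (len > 0 && dend > n) stop_format(sprintf("truncated DICOM element in %s", path))
    val <- if (len > 0) raw[dstart:dend] else raw(0)
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "0002,0010") ts <- trimws(rawToChar(val[val != as.raw(0)]))
    if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
      out[[key]] <- dcm_u16(val, 1L)
    } else if (key %in% c("0028,0030", "0020,0032", "0028,1052", "0028,1053",
                          "0018,0050")) {
      out[[key]] <- as.numeric(strsplit(trimws(rawToChar(val)), "\\\\")[[1]])
    } else if (key == "7fe0,0010") {
      out[["pixel_raw"]] <- val
    }
    pos <- dstart + len
    if (meta && !is.null(ts) && pos <= n && dcm_u16(raw, pos) != 2L) {
      if (identical(ts, "1.2.840.10008.1.2")) {
        explicit <- FALSE
      } else if (!identical(ts, "1.2.840.10008.1.2.1")) {
        stop_format(sprintf("unsupported DICOM transfer syntax '%s' in %s", ts, path))
      }
    }
  }
  required <- c("0028,0010", "0028,0011", "0028,0030", "0020,0032", "pixel_raw")
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    stop_format(sprintf("DICOM file %s lacks required elements: %s",
                        path, paste(missing, collapse = ", ")))
  }
  bits <- out[["0028,0100"]] %||% 16L
  if (bits != 16L) stop_format("only 16-bit DICOM pixel data is supported.")
  signed <- (out[["0028,0103"]] %||% 1L) == 1L
  rows <- out[["0028,0010"]]
  cols <- out[["0028,0011"]]
  stored <- readBin(out$pixel_raw, "integer", n = rows * cols, size = 2L,
                    signed = signed, endian = "little")
  if (length(stored) != rows * cols) {
    stop_format(sprintf("pixel data size mismatch in %s", path))
  }
  slope <- (out[["0028,1053"]] %||% 1)[1]
  intercept <- (out[["0028,1052"]] %||% 0)[1]
  list(
    rows = rows, cols = cols,
    spacing_rc = out[["0028,0030"]], # (row spacing dy, col spacing dx)
    z = out[["0020,0032"]][3],
    slice_thickness = (out[["0018,0050"]] %||% NA_real_)[1],
    hu = matrix(slope * stored + intercept, nrow = rows, ncol = cols, byrow = TRUE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_volume_dicom <- function(dir, padding_value) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop_format(sprintf("no files in DICOM directory %s", dir))
  slices <- lapply(files, read_dicom_file)
  rows <- unique(vapply(slices, `[[`, 0L, "rows"))
  cols <- unique(vapply(slices, `[[`, 0L, "cols"))
  if (length(rows) != 1L || length(cols) != 1L) {
    stop_format("DICOM series has inconsistent matrix sizes.")
  }
  sp <- unique(t(vapply(slices, function(s) round(s$spacing_rc, 6), numeric(2))))
  if (nrow(sp) != 1L) {
    stop_format("DICOM series has inconsistent in-plane pixel spacing.")
  }
  z <- vapply(slices, `[[`, 0, "z")
  ord <- order(z)
  z <- z[ord]
  slices <- slices[ord]
  if (length(z) > 1 && any(diff(z) <= 0)) {
    stop_format("DICOM slice positions are not strictly monotonic.")
  }
  dz <- if (length(z) > 1) {
    dzs <- diff(z)
    if (max(dzs) - min(dzs) > 1e-3 * mean(dzs)) {
      stop_format("DICOM slice positions are not evenly spaced.")
    }
    mean(dzs)
  } else {
    slices[[1]]$slice_thickness %||% 1
  }
  if (!is.finite(dz) || dz <= 0) dz <- 1
  vox <- array(0, dim = c(length(slices), rows, cols))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]$hu
  ct_volume(vox, spacing_mm = c(dz, sp[1, 1], sp[1, 2]),
            kernel_label = "dicom", padding_value = padding_value,
            origin_mm = z[1])
}
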