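# Shared fixtures, all generated in code.

# small uniform volume with optional seeded noise
toy_volume <- function(value = -870, dim3 = c(4, 16, 16), noise_sd = 0,
                       seed = 1, spacing = c(1, 1, 1)) {
  vox <- array(value, dim = dim3)
  if (noise_sd > 0) {
    set.seed(seed)
    vox <- vox + array(rnorm(prod(dim3), 0, noise_sd), dim = dim3)
  }
  ct_volume(vox, spacing_mm = spacing)
}

# tiny network configuration that trains in seconds
tiny_net <- function(base = 4, res = 2, down = 2) {
  network_config(n_down = down, n_residual_blocks = res, base_channels = base)
}

# small synthetic pair set: soft = smoothed-ish target derived from sharp
toy_pairs <- function(n = 8, hw = 32, seed = 7) {
  spec <- thorax_phantom_spec(hw, hw, jitter = 0.05, seed = seed)
  ph <- make_phantom(spec, shape = c(n, hw, hw), seed = seed)
  sharp <- simulate_scan(ph$volume, kernel_diff_params(), "sharp", seed = seed)
  soft <- simulate_scan(ph$volume, kernel_diff_params(), "soft", seed = seed + 1)
  slice_pair_set(sharp$voxels, soft$voxels, seq_len(n), source_id = "toy")
}

# Minimal explicit-VR little-endian DICOM writer for reader tests.
# Emits only the tags the package's reader consumes.
write_test_dicom <- function(path, pixels, slope = 1, intercept = -1024,
                             spacing = c(0.7, 0.8), z = 0,
                             implicit = FALSE) {
  stopifnot(is.matrix(pixels))
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  pad_even <- function(s) if (nchar(s) %% 2 == 1) paste0(s, " ") else s
  el_expl <- function(group, elem, vr, value_raw) {
    head <- c(u16(group), u16(elem), charToRaw(vr))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      c(head, raw(2), u32(length(value_raw)), value_raw)
    } else {
      c(head, u16(length(value_raw)), value_raw)
    }
  }
  el_impl <- function(group, elem, vr, value_raw) {
    c(u16(group), u16(elem), u32(length(value_raw)), value_raw)
  }
  el <- if (implicit) el_impl else el_expl
  ds <- function(...) charToRaw(pad_even(paste(..., sep = "\\")))
  stored <- writeBin(as.integer(round(t(pixels))), raw(), size = 2,
                     endian = "little")
  ts <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"
  ts_raw <- charToRaw(ts)
  if (length(ts_raw) %% 2 == 1) ts_raw <- c(ts_raw, raw(1))
  meta <- el_expl(0x0002, 0x0010, "UI", ts_raw) # meta always explicit
  body <- c(
    el(0x0018, 0x0050, "DS", ds("1.0")),
    el(0x0020, 0x0032, "DS", ds("0", "0", format(z))),
    el(0x0028, 0x0010, "US", u16(nrow(pixels))),
    el(0x0028, 0x0011, "US", u16(ncol(pixels))),
    el(0x0028, 0x0030, "DS", ds(format(spacing[1]), format(spacing[2]))),
    el(0x0028, 0x0100, "US", u16(16)),
    el(0x0028, 0x0103, "US", u16(1)),
    el(0x0028, 0x1052, "DS", ds(format(intercept))),
    el(0x0028, 0x1053, "DS", ds(format(slope))),
    el(0x7fe0, 0x0010, "OW", stored)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}
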