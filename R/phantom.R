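#' Phantom specification for the paired-kernel simulator
#'
#' Describes a piecewise-constant object as a list of in-plane geometric
#' regions painted, in order, over a uniform background. Geometries:
#' `ellipse` (axis-aligned, semi-axes in voxels), `rectangle` (half-extents
#' in voxels), and `disk_cluster` (`n_disks` disks of radius `disk_radius`
#' scattered inside the ellipse defined by center/extent; placement uses the
#' rasterisation seed).
#'
#' @param regions list of regions; each a list with `name`, `geometry`
#'   (`"ellipse"`, `"rectangle"`, `"disk_cluster"`), `center = c(row, col)`,
#'   `extent = c(semi_row, semi_col)` in voxels, `mean_hu`, and for clusters
#'   `n_disks` and `disk_radius`. An optional `z_profile` function
#'   `f(t) -> scale` (t in 0..1 along the slice axis) scales the extent per
#'   slice, so the object tapers like a thorax.
#' @param background_hu background HU (default -1000, air).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(regions, background_hu = -1000) {
  for (r in regions) {
    if (!all(c("name", "geometry", "center", "extent", "mean_hu") %in% names(r))) {
      stop_param("each region needs name, geometry, center, extent, mean_hu.")
    }
    if (!r$geometry %in% c("ellipse", "rectangle", "disk_cluster")) {
      stop_param(sprintf("unknown geometry '%s'.", r$geometry))
    }
    if (r$mean_hu < -1024 || r$mean_hu > 1500) {
      stop_param("region mean HU must lie in [-1024, 1500].")
    }
  }
  structure(list(regions = regions, background_hu = background_hu),
            class = "phantom_spec")
}

#' Default thorax-like phantom specification
#'
#' A stylised axial thorax spanning every analysis band used in validation:
#' air (-1000), emphysema clusters (-970), lung parenchyma (-870),
#' subcutaneous fat body (-100), pectoral muscle (+50), coronary
#' calcification (+400), and vertebral bone (+700) HU. `jitter` perturbs
#' region centers and extents by a relative fraction (seeded), emulating
#' anatomical variation between subjects.
#'
#' @param nrow,ncol in-plane phantom size in voxels (>= 16).
#' @param jitter relative geometric perturbation (0 = none; 0.1 typical).
#' @param seed seed for the jitter draws.
#' @return a [phantom_spec()].
#' @export
thorax_phantom_spec <- function(nrow = 64, ncol = 64, jitter = 0, seed = 0) {
  if (nrow < 16 || ncol < 16) stop_param("phantom must be at least 16 voxels in-plane.")
  cy <- nrow / 2 + 0.5
  cx <- ncol / 2 + 0.5
  taper <- function(t) 0.85 + 0.15 * sin(pi * pmin(pmax(t, 0), 1))
  base <- list(
    list(name = "body", geometry = "ellipse", center = c(cy, cx),
         extent = c(0.44 * nrow, 0.47 * ncol), mean_hu = -100),
    list(name = "muscle_left", geometry = "rectangle",
         center = c(0.17 * nrow, 0.32 * ncol),
         extent = c(0.055 * nrow, 0.12 * ncol), mean_hu = 50),
    list(name = "muscle_right", geometry = "rectangle",
         center = c(0.17 * nrow, 0.68 * ncol),
         extent = c(0.055 * nrow, 0.12 * ncol), mean_hu = 50),
    list(name = "lung_left", geometry = "ellipse",
         center = c(0.52 * nrow, 0.30 * ncol),
         extent = c(0.26 * nrow, 0.15 * ncol), mean_hu = -870,
         z_profile = taper),
    list(name = "lung_right", geometry = "ellipse",
         center = c(0.52 * nrow, 0.70 * ncol),
         extent = c(0.26 * nrow, 0.15 * ncol), mean_hu = -870,
         z_profile = taper),
    list(name = "emphysema_left", geometry = "disk_cluster",
         center = c(0.52 * nrow, 0.30 * ncol),
         extent = c(0.18 * nrow, 0.10 * ncol), mean_hu = -970,
         n_disks = 3, disk_radius = max(2.5, 0.055 * nrow)),
    list(name = "emphysema_right", geometry = "disk_cluster",
         center = c(0.52 * nrow, 0.70 * ncol),
         extent = c(0.18 * nrow, 0.10 * ncol), mean_hu = -970,
         n_disks = 3, disk_radius = max(2.5, 0.055 * nrow)),
    list(name = "airway", geometry = "ellipse",
         center = c(0.38 * nrow, cx),
         extent = c(0.045 * nrow, 0.045 * ncol), mean_hu = -1000),
    list(name = "calcification", geometry = "ellipse",
         center = c(0.55 * nrow, 0.55 * ncol),
         extent = c(0.035 * nrow, 0.035 * ncol), mean_hu = 400),
    list(name = "bone", geometry = "ellipse",
         center = c(0.80 * nrow, cx),
         extent = c(0.075 * nrow, 0.095 * ncol), mean_hu = 700)
  )
  if (jitter > 0) {
    base <- with_seed(seed, lapply(base, function(r) {
      r$center <- r$center * (1 + jitter * stats::runif(2, -1, 1))
      r$extent <- r$extent * (1 + jitter * stats::runif(2, -1, 1))
      r
    }))
  }
  phantom_spec(base, background_hu = -1000)
}

#' Rasterise a phantom specification into a noiseless volume and label mask
#'
#' Paints the regions of `spec` in order onto a uniform background,
#' producing a piecewise-constant HU volume (the simulation ground truth)
#' and an integer label mask (label i = i-th region; later regions
#' overwrite earlier ones where they overlap). Deterministic given `seed`,
#' which drives only the disk-cluster placements.
#'
#' @param spec a [phantom_spec()].
#' @param shape volume shape `(n_slice, n_row, n_col)`; in-plane sizes >= 16.
#' @param spacing_mm voxel spacing `(dz, dy, dx)` in mm.
#' @param seed integer seed for stochastic geometry.
#' @return list with elements `volume` (a [ct_volume()]) and `mask`
#'   (a [region_mask()]).
#' @export
#' @examples
#' ph <- make_phantom(thorax_phantom_spec(32, 32), shape = c(2, 32, 32), seed = 1)
#' sort(unique(as.vector(ph$volume$voxels)))
make_phantom <- function(spec, shape = c(8, 64, 64), spacing_mm = c(1, 1, 1),
                         seed = 0) {
  if (!inherits(spec, "phantom_spec")) stop_param("`spec` must be a phantom_spec.")
  if (length(shape) != 3L || any(shape < 1) || any(shape[2:3] < 16)) {
    stop_param("`shape` must be (n_slice, n_row, n_col) with in-plane sizes >= 16.")
  }
  ns <- shape[1]; nr <- shape[2]; nc <- shape[3]
  rr <- matrix(seq_len(nr), nrow = nr, ncol = nc)
  cc <- matrix(seq_len(nc), nrow = nr, ncol = nc, byrow = TRUE)
  vox <- array(spec$background_hu, dim = shape)
  lab <- array(0L, dim = shape)
  seeds <- derive_seeds(seed, length(spec$regions))
  for (k in seq_along(spec$regions)) {
    r <- spec$regions[[k]]
    # cluster disk centres are fixed per region (not per slice)
    centers <- NULL
    if (r$geometry == "disk_cluster") {
      nd <- r$n_disks %||% 3L
      centers <- with_seed(seeds[k], {
        th <- stats::runif(nd, 0, 2 * pi)
        rad <- sqrt(stats::runif(nd))
        cbind(r$center[1] + rad * (r$extent[1] - r$disk_radius) * sin(th),
              r$center[2] + rad * (r$extent[2] - r$disk_radius) * cos(th))
      })
    }
    for (s in seq_len(ns)) {
      t <- if (ns > 1) (s - 1) / (ns - 1) else 0.5
      sc <- if (!is.null(r$z_profile)) r$z_profile(t) else 1
      ext <- pmax(r$extent * sc, 0.5)
      inside <- switch(
        r$geometry,
        ellipse = ((rr - r$center[1]) / ext[1])^2 +
          ((cc - r$center[2]) / ext[2])^2 <= 1,
        rectangle = abs(rr - r$center[1]) <= ext[1] &
          abs(cc - r$center[2]) <= ext[2],
        disk_cluster = {
          m <- matrix(FALSE, nr, nc)
          for (d in seq_len(nrow(centers))) {
            m <- m | ((rr - centers[d, 1])^2 + (cc - centers[d, 2])^2 <=
                        r$disk_radius^2)
          }
          m
        }
      )
      if (any(inside)) {
        sl <- vox[s, , ]; sl[inside] <- r$mean_hu; vox[s, , ] <- sl
        ll <- lab[s, , ]; ll[inside] <- k; lab[s, , ] <- ll
      }
    }
  }
  names <- vapply(spec$regions, `[[`, "", "name")
  list(
    volume = ct_volume(vox, spacing_mm = spacing_mm, kernel_label = "phantom",
                       padding_value = -2048),
    mask = region_mask(lab, setNames(names, as.character(seq_along(names))))
  )
}
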