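test_that("make_phantom rasterises piecewise-constant regions deterministically", {
  spec <- phantom_spec(list(
    list(name = "lesion", geometry = "ellipse", center = c(16, 16),
         extent = c(5, 5), mean_hu = -950)
  ), background_hu = -870)
  ph <- make_phantom(spec, shape = c(2, 32, 32), seed = 3)
  expect_setequal(unique(as.vector(ph$volume$voxels)), c(-870, -950))
  expect_equal(sort(unique(as.vector(ph$mask$labels))), c(0L, 1L))

  ph2 <- make_phantom(spec, shape = c(2, 32, 32), seed = 3)
  expect_identical(ph$volume$voxels, ph2$volume$voxels)

  # default thorax phantom: noiseless region means match the declared values
  ts <- thorax_phantom_spec(64, 64)
  th <- make_phantom(ts, shape = c(2, 64, 64), seed = 1)
  for (k in seq_along(ts$regions)) {
    sel <- th$mask$labels == k
    if (any(sel)) {
      expect_equal(unique(th$volume$voxels[sel]), ts$regions[[k]]$mean_hu)
    }
  }
})

test_that("phantom_spec validates geometry and HU ranges", {
  expect_error(phantom_spec(list(list(name = "x", geometry = "blob",
                                      center = c(1, 1), extent = c(1, 1),
                                      mean_hu = 0))),
               class = "kernelconvert_param_error")
  expect_error(phantom_spec(list(list(name = "x", geometry = "ellipse",
                                      center = c(1, 1), extent = c(1, 1),
                                      mean_hu = 2000))),
               class = "kernelconvert_param_error")
})

test_that("degenerate kernel parameters make sharp and soft scans identical", {
  ph <- make_phantom(thorax_phantom_spec(32, 32), shape = c(2, 32, 32), seed = 1)
  p0 <- kernel_diff_params(boost_gain = 0, noise_sd_soft = 3, noise_sd_sharp = 3,
                           smoothing_fwhm_soft = 0)
  soft <- simulate_scan(ph$volume, p0, "soft", seed = 9)
  sharp <- simulate_scan(ph$volume, p0, "sharp", seed = 9)
  expect_equal(soft$voxels, sharp$voxels)
})

test_that("simulated noise has the requested standard deviation", {
  flat <- ct_volume(array(-870, c(1, 64, 64)))
  p <- kernel_diff_params(boost_gain = 0, noise_sd_soft = 6, noise_sd_sharp = 10,
                          smoothing_fwhm_soft = 0)
  scan <- simulate_scan(flat, p, "soft", seed = 11)
  s <- sd(scan$voxels)
  # chi-square 99% bounds for n = 4096 are well inside [5, 7]
  expect_gt(s, 5)
  expect_lt(s, 7)
})

test_that("the sharp kernel amplifies high spatial frequencies", {
  ph <- make_phantom(thorax_phantom_spec(64, 64), shape = c(2, 64, 64), seed = 2)
  p <- kernel_diff_params(boost_gain = 1.5, noise_sd_soft = 0,
                          noise_sd_sharp = 0, smoothing_fwhm_soft = 1.5)
  sharp <- simulate_scan(ph$volume, p, "sharp", seed = 0)
  soft <- simulate_scan(ph$volume, p, "soft", seed = 0)
  grad_mag <- function(v) {
    sl <- v$voxels[1, , ]
    mean(abs(diff(sl))) + mean(abs(t(diff(t(sl)))))
  }
  expect_gt(grad_mag(sharp), grad_mag(soft))
  # sharp noise sd exceeds soft noise sd on uniform regions when params say so
  flat <- ct_volume(array(-870, c(1, 64, 64)))
  pn <- kernel_diff_params(boost_gain = 0, smoothing_fwhm_soft = 0)
  expect_gt(sd(simulate_scan(flat, pn, "sharp", seed = 5)$voxels),
            sd(simulate_scan(flat, pn, "soft", seed = 5)$voxels))
})

test_that("soft smoothing preserves interior region means within 1 HU", {
  spec <- phantom_spec(list(
    list(name = "core", geometry = "rectangle", center = c(32, 32),
         extent = c(20, 20), mean_hu = -100)
  ), background_hu = -870)
  ph <- make_phantom(spec, shape = c(1, 64, 64), seed = 0)
  p <- kernel_diff_params(noise_sd_soft = 0, noise_sd_sharp = 0)
  soft <- simulate_scan(ph$volume, p, "soft", seed = 0)
  interior <- soft$voxels[1, 22:42, 22:42] # eroded well beyond the PSF
  expect_lt(abs(mean(interior) - (-100)), 1)
})

test_that("repeated scans share the phantom but differ in noise", {
  ph <- make_phantom(thorax_phantom_spec(32, 32), shape = c(2, 32, 32), seed = 1)
  scans <- repeated_scans(ph$volume, kernel_diff_params(), "soft", n = 6, seed = 4)
  expect_length(scans, 6)
  for (i in 2:6) {
    expect_equal(dim(scans[[i]]$voxels), dim(scans[[1]]$voxels))
    expect_false(identical(scans[[i]]$voxels, scans[[1]]$voxels))
  }
  # zero noise: all scans identical
  p0 <- kernel_diff_params(noise_sd_soft = 0, noise_sd_sharp = 0)
  z <- repeated_scans(ph$volume, p0, "soft", n = 3, seed = 4)
  expect_identical(z[[1]]$voxels, z[[2]]$voxels)
  expect_error(repeated_scans(ph$volume, n = 1, seed = 1),
               class = "kernelconvert_param_error")
})

test_that("averaging repeated scans converges toward the noiseless phantom", {
  ph <- make_phantom(thorax_phantom_spec(32, 32), shape = c(1, 32, 32), seed = 1)
  p <- kernel_diff_params(boost_gain = 0, smoothing_fwhm_soft = 0,
                          noise_sd_soft = 8, noise_sd_sharp = 8)
  mad_at <- function(n) {
    scans <- repeated_scans(ph$volume, p, "soft", n = n, seed = 2)
    avg <- Reduce(`+`, lapply(scans, `[[`, "voxels")) / n
    mean(abs(avg - ph$volume$voxels))
  }
  expect_lt(mad_at(64), mad_at(4))
})

test_that("identical seeds give identical simulated scans", {
  ph <- make_phantom(thorax_phantom_spec(32, 32), shape = c(2, 32, 32), seed = 1)
  a <- simulate_scan(ph$volume, kernel_diff_params(), "sharp", seed = 123)
  b <- simulate_scan(ph$volume, kernel_diff_params(), "sharp", seed = 123)
  expect_identical(a$voxels, b$voxels)
})
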