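test_that("LAV% counts strictly sub-threshold lung voxels", {
  lung <- array(TRUE, c(1, 2, 2))
  all_low <- ct_volume(array(-1000, c(1, 2, 2)))
  expect_equal(lav_percent(all_low, lung)$value, 100)
  none <- ct_volume(array(-900, c(1, 2, 2)))
  expect_equal(lav_percent(none, lung)$value, 0)
  one <- ct_volume(array(c(-960, -900, -900, -900), c(1, 2, 2)))
  r <- lav_percent(one, lung)
  expect_equal(r$value, 25)
  expect_equal(r$n_voxels_region, 4)
  expect_equal(r$n_voxels_positive, 1)
  # boundary voxel at exactly -950 is excluded
  bound <- ct_volume(array(c(-950, -900, -900, -900), c(1, 2, 2)))
  expect_equal(lav_percent(bound, lung)$value, 0)
  expect_error(lav_percent(one, array(FALSE, c(1, 2, 2))),
               class = "kernelconvert_data_error")
})

test_that("low_attenuation_mask is contained in the lung mask", {
  vox <- array(c(-1000, -960, -940, -800), c(1, 2, 2))
  lung <- array(c(TRUE, TRUE, TRUE, FALSE), c(1, 2, 2))
  m <- low_attenuation_mask(ct_volume(vox), lung)
  expect_equal(sum(m$labels), 2)
  expect_true(all(m$labels[!lung] == 0))
  allv <- ct_volume(array(-1000, c(1, 2, 2)))
  expect_equal(low_attenuation_mask(allv, array(TRUE, c(1, 2, 2)))$labels > 0,
               array(TRUE, c(1, 2, 2)))
})

test_that("Dice matches hand counts and its edge conventions", {
  d <- c(1, 2, 2)
  a <- array(c(TRUE, TRUE, FALSE, FALSE), d)
  b <- array(c(FALSE, TRUE, TRUE, FALSE), d)
  expect_equal(dice(a, b), 0.5) # A = {v1,v2}, B = {v2,v3}
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, array(c(FALSE, FALSE, TRUE, TRUE), d)), 0)
  expect_equal(dice(array(FALSE, d), array(FALSE, d)), 1) # both empty
  expect_equal(dice(a, b), dice(b, a)) # symmetry
  expect_error(dice(a, array(TRUE, c(1, 2, 3))),
               class = "kernelconvert_shape_error")
})

test_that("IMAT% counts strictly sub--30 HU muscle voxels", {
  muscle <- array(TRUE, c(1, 2, 2))
  all_m <- ct_volume(array(50, c(1, 2, 2)))
  expect_equal(imat_percent(all_m, muscle)$value, 0)
  half <- ct_volume(array(c(-100, -100, 50, 50), c(1, 2, 2)))
  expect_equal(imat_percent(half, muscle)$value, 50)
  bound <- ct_volume(array(c(-30, 50, 50, 50), c(1, 2, 2)))
  expect_equal(imat_percent(bound, muscle)$value, 0)
})

test_that("CAC volume multiplies strict supra-130 counts by voxel volume", {
  roi <- array(TRUE, c(10, 2, 2))
  vox <- array(0, c(10, 2, 2))
  vox[, 1, 1] <- 200 # 10 voxels above threshold
  v <- ct_volume(vox, spacing_mm = c(1.0, 0.7, 0.7))
  r <- cac_volume(v, roi)
  expect_equal(r$value, 10 * 0.49)
  expect_equal(r$n_voxels_positive, 10)
  none <- ct_volume(array(0, c(1, 2, 2)))
  expect_equal(cac_volume(none, array(TRUE, c(1, 2, 2)))$value, 0)
  exact <- ct_volume(array(130, c(1, 2, 2)))
  expect_equal(cac_volume(exact, array(TRUE, c(1, 2, 2)))$value, 0)
})

test_that("indices are monotone in qualifying voxels and label-invariant", {
  vox <- array(-900, c(1, 4, 4))
  lung1 <- region_mask(array(1L, c(1, 4, 4)))
  lung9 <- region_mask(array(9L, c(1, 4, 4))) # renumbered labels
  v <- ct_volume(vox)
  expect_equal(lav_percent(v, lung1)$value, lav_percent(v, lung9)$value)
  vox2 <- vox
  vox2[1, 1, 1] <- -960
  expect_gt(lav_percent(ct_volume(vox2), lung1)$value,
            lav_percent(v, lung1)$value)
})
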