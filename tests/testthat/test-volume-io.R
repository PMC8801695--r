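test_that("ct_volume enforces its invariants", {
  expect_error(ct_volume(matrix(0, 2, 2)), class = "kernelconvert_shape_error")
  expect_error(ct_volume(array(0, c(2, 2, 2)), spacing_mm = c(1, -1, 1)),
               class = "kernelconvert_param_error")
  expect_error(ct_volume(array(c(0, NaN), c(2, 1, 1))),
               class = "kernelconvert_data_error")
  v <- ct_volume(array(-870L, c(2, 3, 4)), spacing_mm = c(0.5, 0.7, 0.7))
  expect_type(v$voxels, "double")
  expect_equal(dim(v$voxels), c(2, 3, 4))
})

test_that("validity mask excludes padding voxels", {
  vox <- array(-870, c(1, 2, 2))
  vox[1, 1, 1] <- -2048
  v <- ct_volume(vox)
  expect_equal(sum(validity_mask(v)), 3)
})

test_that("truncate_hu clamps, preserves metadata, and is idempotent", {
  v <- ct_volume(array(c(500, -1000, 0, 250), c(4, 1, 1)),
                 spacing_mm = c(2, 1, 1))
  t1 <- truncate_hu(v, -300, 300)
  expect_equal(as.vector(t1$voxels), c(300, -300, 0, 250))
  expect_equal(t1$spacing_mm, v$spacing_mm)
  t2 <- truncate_hu(t1, -300, 300)
  expect_equal(t2$voxels, t1$voxels)
  inside <- ct_volume(array(c(-100, 50), c(2, 1, 1)))
  expect_equal(truncate_hu(inside, -300, 300)$voxels, inside$voxels)
  expect_error(truncate_hu(v, 300, -300), class = "kernelconvert_param_error")
})

test_that("NIfTI write/read round-trips volumes and masks exactly", {
  set.seed(4)
  v <- ct_volume(array(rnorm(8 * 16 * 16, -500, 300), c(8, 16, 16)),
                 spacing_mm = c(1, 0.7, 0.7), origin_mm = 12.5)
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(v2$spacing_mm, v$spacing_mm, tolerance = 1e-6)
  expect_equal(v2$origin_mm, v$origin_mm, tolerance = 1e-6)

  m <- region_mask(array(sample(0:3, 8 * 16 * 16, TRUE), c(8, 16, 16)))
  fm <- tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  m2 <- read_mask(fm)
  expect_identical(m2$labels, m$labels)

  bad <- v
  bad$voxels[1] <- NaN
  expect_error(write_volume(bad, tempfile(fileext = ".nii")),
               class = "kernelconvert_data_error")
})

test_that("DICOM reader applies rescale and orders slices by position", {
  dir <- file.path(tempdir(), "dcm1")
  dir.create(dir, showWarnings = FALSE)
  px <- matrix(24L, 8, 8)
  # write out of z order; reader must sort by ImagePositionPatient
  write_test_dicom(file.path(dir, "b.dcm"), px, slope = 1,
                   intercept = -1024, z = 1)
  write_test_dicom(file.path(dir, "a.dcm"), px + 100L, slope = 1,
                   intercept = -1024, z = 0)
  v <- read_volume(dir, format = "dicom_series")
  # HU = slope * stored + intercept
  expect_equal(v$voxels[1, 1, 1], -900) # stored 124 at z = 0
  expect_equal(v$voxels[2, 1, 1], -1000) # stored 24 at z = 1
  expect_equal(v$spacing_mm, c(1, 0.7, 0.8))
  unlink(dir, recursive = TRUE)
})

test_that("DICOM reader handles implicit VR and rejects inconsistent series", {
  dir <- file.path(tempdir(), "dcm2")
  dir.create(dir, showWarnings = FALSE)
  write_test_dicom(file.path(dir, "a.dcm"), matrix(0L, 4, 4), z = 0,
                   implicit = TRUE)
  v <- read_volume(dir)
  expect_equal(v$voxels[1, 1, 1], -1024)
  unlink(dir, recursive = TRUE)

  dir <- file.path(tempdir(), "dcm3")
  dir.create(dir, showWarnings = FALSE)
  write_test_dicom(file.path(dir, "a.dcm"), matrix(0L, 4, 4), z = 0,
                   spacing = c(0.7, 0.7))
  write_test_dicom(file.path(dir, "b.dcm"), matrix(0L, 4, 4), z = 1,
                   spacing = c(0.9, 0.9))
  expect_error(read_volume(dir), class = "kernelconvert_format_error")
  unlink(dir, recursive = TRUE)

  dir <- file.path(tempdir(), "dcm4")
  dir.create(dir, showWarnings = FALSE)
  write_test_dicom(file.path(dir, "a.dcm"), matrix(0L, 4, 4), z = 0)
  write_test_dicom(file.path(dir, "b.dcm"), matrix(0L, 4, 4), z = 0)
  expect_error(read_volume(dir), class = "kernelconvert_format_error")
  unlink(dir, recursive = TRUE)
})

test_that("pair_slices yields one pair per soft slice at matched locations", {
  hw <- 8
  sharp <- ct_volume(array(seq_len(600 * hw * hw), c(600, hw, hw)),
                     spacing_mm = c(0.5, 1, 1))
  soft <- ct_volume(array(0, c(300, hw, hw)), spacing_mm = c(1, 1, 1))
  ps <- pair_slices(sharp, soft)
  expect_equal(length(ps), 300)
  # aligned origins: soft slice i matches sharp slice 2i - 1
  expect_equal(ps$sharp[1, , ], sharp$voxels[1, , ])
  expect_equal(ps$sharp[10, , ], sharp$voxels[19, , ])
})

test_that("pair_slices matches by nearest physical location with offsets", {
  hw <- 8
  sharp_vox <- array(0, c(10, hw, hw))
  for (i in 1:10) sharp_vox[i, , ] <- i
  sharp <- ct_volume(sharp_vox, spacing_mm = c(0.5, 1, 1), origin_mm = 0)
  soft <- ct_volume(array(0, c(5, hw, hw)), spacing_mm = c(1, 1, 1),
                    origin_mm = 0.25)
  ps <- pair_slices(sharp, soft)
  # ties at 0.25 mm resolve to the lower index: sharp slices 1,3,5,7,9
  expect_equal(ps$sharp[, 1, 1], c(1, 3, 5, 7, 9))
})

test_that("pair_slices rejects wrong spacing ratios and shapes", {
  a <- toy_volume(dim3 = c(4, 8, 8))
  expect_error(pair_slices(a, a), class = "kernelconvert_data_error")
  sharp <- toy_volume(dim3 = c(8, 8, 8), spacing = c(0.5, 1, 1))
  wrong <- toy_volume(dim3 = c(4, 8, 10), spacing = c(1, 1, 1))
  expect_error(pair_slices(sharp, wrong), class = "kernelconvert_shape_error")
})
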