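test_that("blend weights hit the hand-computed knot and ramp values", {
  sp <- blend_spec()
  # default orientation: partial model owns the middle band
  expect_equal(blend_weight(0, sp), 1)
  expect_equal(blend_weight(-170, sp), 1)
  expect_equal(blend_weight(170, sp), 1)
  expect_equal(blend_weight(-200, sp), 0.5)
  expect_equal(blend_weight(200, sp), 0.5)
  expect_equal(blend_weight(-230, sp), 0)
  expect_equal(blend_weight(230, sp), 0)
  expect_equal(blend_weight(-500, sp), 0)
  # verbatim orientation: the printed expression assigns the extremes
  vb <- blend_spec(orientation = "verbatim")
  expect_equal(blend_weight(-230, vb), 1)
  expect_equal(blend_weight(0, vb), 0)
  expect_equal(blend_weight(230, vb), 1)
  expect_equal(blend_weight(-200, vb), 0.5)
})

test_that("blend weight is in [0,1], continuous, and mirror-symmetric", {
  grid <- seq(-1200, 1200, by = 0.5)
  wm <- blend_weight(grid, blend_spec())
  wv <- blend_weight(grid, blend_spec(orientation = "verbatim"))
  expect_true(all(wm >= 0 & wm <= 1))
  expect_true(all(wv >= 0 & wv <= 1))
  # piecewise-linear continuity: steps bounded by slope * grid step
  expect_lt(max(abs(diff(wm))), 0.5 / 60 + 1e-9)
  # the two orientations are mirror images at the default knots
  expect_equal(wm, 1 - wv, tolerance = 1e-12)
})

test_that("fuse is a voxelwise convex combination under the printed rule", {
  sp <- blend_spec(weight_source = "partial")
  full <- matrix(c(500, 500, 500), 1)
  part <- matrix(c(0, 290, -200), 1)
  out <- fuse(full, part, sp)
  expect_equal(out[1, 1], 0) # w = 1 at 0 HU: partial wins
  expect_equal(out[1, 2], 500) # w = 0 beyond inner_hi + ramp = 230
  expect_equal(out[1, 3], 0.5 * -200 + 0.5 * 500) # mid-ramp at -200

  # identical inputs are a fixed point for any weight source
  img <- matrix(rnorm(64, 0, 300), 8)
  expect_equal(fuse(img, img, blend_spec()), img)
  expect_equal(fuse(img, img, sp), img)

  # output bounded between the two inputs voxelwise
  set.seed(1)
  a <- matrix(rnorm(256, 0, 400), 16)
  b <- matrix(rnorm(256, 0, 400), 16)
  for (src in c("full", "partial")) {
    o <- fuse(a, b, blend_spec(weight_source = src))
    expect_true(all(o >= pmin(a, b) - 1e-9 & o <= pmax(a, b) + 1e-9))
  }
  expect_error(fuse(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "kernelconvert_shape_error")
})

test_that("fuse_multi assigns voxels by window ownership with cross-fades", {
  sp <- blend_spec()
  d <- c(1, 4, 4)
  img1 <- array(-500, d)
  img2 <- array(-480, d)
  outs <- list(list(img = img1, window = c(-2048, 0)),
               list(img = img2, window = c(0, 1500)))
  out <- fuse_multi(outs, sp)
  # reference well below the boundary: sole interior owner wins
  expect_equal(out, img1)

  # identical outputs are a fixed point (weights sum to 1)
  same <- array(200, d)
  expect_equal(fuse_multi(list(list(img = same, window = c(-2048, 0)),
                               list(img = same, window = c(0, 1500))), sp),
               same)

  # continuity across the boundary: outputs close in value blend smoothly
  v <- seq(-80, 80, by = 1)
  o <- vapply(v, function(x) {
    fuse_multi(list(list(img = array(x, c(1, 1, 1)), window = c(-2048, 0)),
                    list(img = array(x + 10, c(1, 1, 1)), window = c(0, 1500))),
               sp)[1, 1, 1]
  }, 0)
  expect_lt(max(abs(diff(o))), 3)

  expect_error(fuse_multi(list(list(img = img1, window = c(-2048, 0))), sp),
               class = "kernelconvert_param_error")
  expect_error(
    fuse_multi(list(list(img = img1, window = c(-2048, -1000)),
                    list(img = img2, window = c(0, 1500))), sp),
    class = "kernelconvert_param_error"
  )
})
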