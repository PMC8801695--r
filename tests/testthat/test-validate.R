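test_that("band_errors summarises differences by reference-band membership", {
  x <- toy_volume(value = -870, dim3 = c(2, 8, 8), noise_sd = 20, seed = 1)
  z <- band_errors(x, x)
  expect_true(all(z$median[!z$empty] == 0))
  expect_true(all(z$q1[!z$empty] == 0 & z$q3[!z$empty] == 0))

  y <- x
  y$voxels <- y$voxels + 5
  z5 <- band_errors(y, x)
  expect_true(all(abs(z5$median[!z5$empty] - 5) < 1e-9))

  ref <- ct_volume(array(c(-900, -400, 0, 400, 800, -1500, rep(0, 2)),
                         c(8, 1, 1)))
  tst <- ref
  z <- band_errors(tst, ref)
  narrow <- z[z$band != "broad[-1000,1000)", ]
  expect_equal(narrow$n, c(1, 1, 3, 1, 1))
  expect_equal(z$n[z$band == "broad[-1000,1000)"], 7) # -1500 falls outside
})

test_that("band intervals are half-open on the reference value", {
  ref <- ct_volume(array(c(-600, -200, 200, -601), c(4, 1, 1)))
  z <- band_errors(ref, ref)
  expect_equal(z$n[z$band == "[-1000,-600)"], 1) # -601 only
  expect_equal(z$n[z$band == "[-600,-200)"], 1) # -600 in, -200 out
  expect_equal(z$n[z$band == "[-200,200)"], 1)
  expect_equal(z$n[z$band == "[200,600)"], 1)
})

test_that("interscan variability pools zero-mean deviations from the average", {
  base <- toy_volume(value = -870, dim3 = c(1, 8, 8))
  d <- array(3, c(1, 8, 8))
  up <- base
  up$voxels <- base$voxels + d
  dn <- base
  dn$voxels <- base$voxels - d
  z <- interscan_variability(list(up, dn))
  allrow <- z[z$band == "all", ]
  expect_equal(allrow$mean, 0, tolerance = 1e-12)
  expect_equal(allrow$n, 2 * 64)
  expect_equal(c(allrow$q1, allrow$q3), c(-3, 3))
  # membership decided by the mean volume: all voxels sit in the lung band
  expect_equal(z$n[z$band == "[-1000,-600)"], 2 * 64)

  same <- interscan_variability(list(base, base, base))
  expect_true(all(same$median[!same$empty] == 0))

  scans <- repeated_scans(make_phantom(thorax_phantom_spec(32, 32),
                                       shape = c(1, 32, 32), seed = 1)$volume,
                          kernel_diff_params(), "soft", n = 5, seed = 3)
  zi <- interscan_variability(scans)
  expect_lt(abs(zi$mean[zi$band == "all"]), 1e-6)
  expect_error(interscan_variability(list(base)),
               class = "kernelconvert_param_error")
})

test_that("compare_to_phantom computes ratios and verdicts", {
  mk <- function(med, q1, q3) {
    tibble::tibble(band = c("a", "b"), lo = 0, hi = 1, n = 10,
                   median = med, q1 = q1, q3 = q3, mean = med, sd = 1,
                   empty = FALSE)
  }
  conv <- mk(c(0, 0), c(-1.5, -5), c(1.5, 5))
  ph <- mk(c(0, 0), c(-1, -0.5), c(1, 0.5))
  v <- compare_to_phantom(conv, ph)
  expect_equal(v$iqr_ratio, c(3 / 2, 10))
  expect_true(v$acceptable[1])
  expect_false(v$acceptable[2])
  ident <- compare_to_phantom(ph, ph)
  expect_true(all(ident$acceptable))
  expect_true(all(ident$iqr_ratio == 1))
  expect_error(compare_to_phantom(conv[1, ], ph),
               class = "kernelconvert_param_error")
})

test_that("bland_altman reports bias and limits of agreement", {
  b <- rnorm(20)
  ba <- bland_altman(b + 2, b)
  expect_equal(ba$bias, 2)
  expect_equal(ba$loa_lo, 2)
  expect_equal(ba$loa_hi, 2)
  # antisymmetry
  set.seed(8)
  a <- rnorm(15)
  c2 <- rnorm(15)
  expect_equal(bland_altman(a, c2)$bias, -bland_altman(c2, a)$bias)
  expect_error(bland_altman(1:3, 1:4), class = "kernelconvert_data_error")
  expect_error(bland_altman(1, 1), class = "kernelconvert_data_error")
})

test_that("bland_altman recovers a known normal difference distribution", {
  set.seed(99)
  n <- 1e4
  b <- rnorm(n, 50, 5)
  a <- b + rnorm(n, 2, 1)
  ba <- bland_altman(a, b)
  expect_gt(ba$bias, 1.9)
  expect_lt(ba$bias, 2.1)
  expect_gt(ba$loa_hi, 3.86)
  expect_lt(ba$loa_hi, 4.06)
  g <- glance(ba)
  expect_equal(g$bias, ba$bias)
  expect_equal(nrow(tidy(ba)), n)
})

test_that("paired t-tests apply the Bonferroni cap and reject degenerate data", {
  set.seed(3)
  ref <- rnorm(10, 1)
  comp <- list(shift = ref - 1 + rnorm(10, 0, 0.3),
               near = ref + rnorm(10, 0, 2))
  out <- paired_t_bonferroni(ref, comp, m = 3)
  expect_equal(out$p_adjusted, pmin(1, 3 * out$p_raw))
  expect_true(all(out$p_adjusted <= 1))
  expect_error(paired_t_bonferroni(ref, comp, m = 1),
               class = "kernelconvert_param_error")
  expect_error(paired_t_bonferroni(ref, list(const = ref + 5)),
               class = "kernelconvert_data_error")
})
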