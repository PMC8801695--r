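test_that("HU normaliser maps window endpoints and round-trips", {
  nm <- hu_normalizer(-2048, 1500)
  expect_equal(normalize_hu(-2048, nm), -1)
  expect_equal(normalize_hu(1500, nm), 1)
  expect_equal(normalize_hu((-2048 + 1500) / 2, nm), 0)
  x <- seq(-2048, 1500, length.out = 1001)
  expect_lt(max(abs(denormalize_hu(normalize_hu(x, nm), nm) - x)), 1e-3)
  # out-of-window values clamp
  expect_equal(denormalize_hu(normalize_hu(c(-5000, 3000), nm), nm),
               c(-2048, 1500))
  expect_error(hu_normalizer(300, -300), class = "kernelconvert_param_error")
})

test_that("network output matches input shape and is bounded", {
  cfg <- tiny_net(base = 8, res = 2, down = 3)
  net <- build_network(cfg, seed = 0)
  x <- array(0, c(64, 64, 1))
  y <- cnn_forward_cpp(net$params, kernelconvert:::cpp_cfg(cfg), x)
  expect_equal(dim(y), c(64, 64, 1))
  set.seed(2)
  xr <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  yr <- cnn_forward_cpp(net$params, kernelconvert:::cpp_cfg(cfg), xr)
  expect_true(all(abs(yr) < 1))
  expect_true(all(is.finite(yr)))
})

test_that("weight initialisation is deterministic and counted correctly", {
  cfg <- tiny_net()
  a <- build_network(cfg, seed = 5)
  b <- build_network(cfg, seed = 5)
  expect_identical(a$params, b$params)
  expect_equal(sum(vapply(a$params, length, 0)), n_network_parameters(cfg))
  # default architecture: 3 down + 9 residual blocks + 3 up
  expect_equal(n_network_parameters(network_config()),
               n_network_parameters(network_config(n_down = 3,
                                                   n_residual_blocks = 9)))
})

test_that("analytic gradients match finite differences", {
  cfg <- network_config(n_down = 1, n_residual_blocks = 1, base_channels = 2,
                        global_residual = FALSE)
  net <- build_network(cfg, seed = 3)
  ccfg <- kernelconvert:::cpp_cfg(cfg)
  set.seed(42)
  X <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  Y <- array(rnorm(8 * 8 * 2) * 0.3, c(8, 8, 2))
  M <- array(1, c(8, 8, 2))
  M[1:2, 1, 1] <- 0
  lg <- cnn_loss_grad_cpp(net$params, ccfg, X, Y, M, 1, 1)
  eps <- 1e-6
  for (pi in seq_along(net$params)) {
    ii <- min(3, length(net$params[[pi]]))
    pp <- net$params
    pp[[pi]][ii] <- pp[[pi]][ii] + eps
    lp <- cnn_loss_grad_cpp(pp, ccfg, X, Y, M, 1, 1)$loss
    pm <- net$params
    pm[[pi]][ii] <- pm[[pi]][ii] - eps
    lm <- cnn_loss_grad_cpp(pm, ccfg, X, Y, M, 1, 1)$loss
    fd <- (lp - lm) / (2 * eps)
    an <- lg$grads[[pi]][ii]
    if (abs(fd) + abs(an) > 1e-7) {
      expect_lt(abs(fd - an) / (abs(fd) + abs(an)), 1e-4)
    }
  }
  # gradient of the global residual variant as well
  cfgr <- network_config(n_down = 1, n_residual_blocks = 1, base_channels = 2)
  netr <- build_network(cfgr, seed = 3)
  ccfgr <- kernelconvert:::cpp_cfg(cfgr)
  lgr <- cnn_loss_grad_cpp(netr$params, ccfgr, X, Y, M, 1, 1)
  pp <- netr$params
  pp[[1]][1] <- pp[[1]][1] + eps
  lp <- cnn_loss_grad_cpp(pp, ccfgr, X, Y, M, 1, 1)$loss
  pm <- netr$params
  pm[[1]][1] <- pm[[1]][1] - eps
  lm <- cnn_loss_grad_cpp(pm, ccfgr, X, Y, M, 1, 1)$loss
  fd <- (lp - lm) / (2 * eps)
  expect_lt(abs(fd - lgr$grads[[1]][1]) / (abs(fd) + 1e-9), 1e-4)
})

test_that("training reduces the loss and is seed-reproducible", {
  pairs <- toy_pairs(n = 8, hw = 32)
  for (sd in c(0, 1, 2)) {
    tc <- train_config(epochs = 4, seed = sd)
    m <- train_converter(pairs, tiny_net(), tc)
    expect_length(m$loss_history, 4)
    expect_lt(m$loss_history[4], m$loss_history[1])
  }
  tc <- train_config(epochs = 3, seed = 0)
  m1 <- train_converter(pairs, tiny_net(), tc)
  m2 <- train_converter(pairs, tiny_net(), tc)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$params, m2$params)
})

test_that("the identity task is learnable above the untrained baseline", {
  pairs <- toy_pairs(n = 6, hw = 32)
  pairs$soft <- pairs$sharp # target = input
  cfg <- tiny_net()
  tc <- train_config(epochs = 4, seed = 0)
  m <- train_converter(pairs, cfg, tc)
  un <- untrained_model(build_network(cfg, seed = 0))
  vol <- ct_volume(pairs$sharp)
  mae <- function(model) {
    mean(abs(convert_volume(model, vol)$voxels - pairs$sharp))
  }
  expect_lt(mae(m), mae(un))
})

test_that("training rejects empty pair sets and records truncation windows", {
  expect_error(train_converter(list(), tiny_net(), train_config()),
               class = "kernelconvert_param_error")
  pairs <- toy_pairs(n = 4, hw = 32)
  tc <- train_config(epochs = 2, seed = 0, truncation = c(-300, 300))
  m <- train_converter(pairs, tiny_net(), tc)
  expect_equal(m$normalizer$window_lo, -300)
  expect_equal(m$normalizer$window_hi, 300)
  expect_match(m$id, "partial")
})

test_that("conversion is deterministic and confined to the model window", {
  pairs <- toy_pairs(n = 4, hw = 32)
  tc <- train_config(epochs = 2, seed = 0, truncation = c(-300, 300))
  m <- train_converter(pairs, tiny_net(), tc)
  vol <- toy_volume(value = -870, dim3 = c(2, 32, 32), noise_sd = 30)
  out1 <- convert_volume(m, vol)
  out2 <- convert_volume(m, vol)
  expect_identical(out1$voxels, out2$voxels)
  expect_true(all(out1$voxels >= -300 & out1$voxels <= 300))
  expect_match(out1$kernel_label, "converted")

  # untrained pipeline on zeros: finite output, same shape
  un <- untrained_model(build_network(tiny_net(), seed = 1))
  z <- convert_volume(un, toy_volume(value = 0, dim3 = c(1, 32, 32)))
  expect_true(all(is.finite(z$voxels)))
  expect_equal(dim(z$voxels), c(1, 32, 32))
})

test_that("conversion pads non-multiple shapes and restores padding voxels", {
  pairs <- toy_pairs(n = 4, hw = 32)
  m <- train_converter(pairs, tiny_net(), train_config(epochs = 2, seed = 0))
  vox <- array(-870, c(1, 24, 20)) # not a multiple of 2^2
  vox[1, 1, 1] <- -2048
  vol <- ct_volume(vox)
  out <- convert_volume(m, vol)
  expect_equal(dim(out$voxels), c(1, 24, 20))
  expect_equal(out$voxels[1, 1, 1], -2048)
})

test_that("model checkpoints round-trip through disk", {
  pairs <- toy_pairs(n = 4, hw = 32)
  m <- train_converter(pairs, tiny_net(), train_config(epochs = 2, seed = 0))
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  vol <- toy_volume(dim3 = c(1, 32, 32), noise_sd = 20)
  expect_identical(convert_volume(m, vol)$voxels,
                   convert_volume(m2, vol)$voxels)
  saveRDS(list(), f)
  expect_error(load_model(f), class = "kernelconvert_format_error")
})
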