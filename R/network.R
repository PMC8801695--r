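#' Network architecture configuration
#'
#' Describes the residual encoder-bottleneck-decoder used for slice-to-slice
#' kernel conversion: a stem convolution, `n_down` stride-2 down-sampling
#' convolutions, `n_residual_blocks` residual blocks at the bottleneck,
#' `n_down` nearest-upsample + convolution up-sampling layers with additive
#' skip connections to the corresponding down layers, and a final 3x3
#' convolution. Instance normalisation and ReLU follow every layer except
#' the last, whose arctan activation (rescaled by 2/pi) bounds the output
#' to the open normalised interval (-1, 1).
#'
#' @param n_down number of down-sampling (and up-sampling) layers.
#' @param n_residual_blocks number of bottleneck residual blocks.
#' @param base_channels channels after the stem; doubled at each
#'   down-sampling. 32 at full scale; 8 for desk-scale experiments.
#' @param use_instance_norm apply instance normalisation after each
#'   convolution except the last.
#' @param final_activation only `"arctan"` is supported.
#' @param skip_connections additive skips between matching down/up levels.
#' @param global_residual add a parameter-free identity path at the output:
#'   `out = (2/pi) * atan(tan(pi/2 * x) + z)` with `x` the normalised input
#'   and `z` the final convolution's output. Instance normalisation discards
#'   absolute intensity levels inside the network; the identity path
#'   re-anchors the output to the input's HU level, so the network learns
#'   the kernel-difference residual. The bounded arctan output is preserved.
#' @return a `network_config` object.
#' @export
network_config <- function(n_down = 3, n_residual_blocks = 9,
                           base_channels = 32, use_instance_norm = TRUE,
                           final_activation = "arctan",
                           skip_connections = TRUE,
                           global_residual = TRUE) {
  if (n_down < 1 || n_residual_blocks < 1 || base_channels < 1) {
    stop_param("layer counts and channel width must be >= 1.")
  }
  if (!identical(final_activation, "arctan")) {
    stop_param("only the arctan final activation is supported.")
  }
  structure(
    list(n_down = as.integer(n_down),
         n_residual_blocks = as.integer(n_residual_blocks),
         n_up = as.integer(n_down),
         base_channels = as.integer(base_channels),
         use_instance_norm = isTRUE(use_instance_norm),
         final_activation = "arctan",
         skip_connections = isTRUE(skip_connections),
         global_residual = isTRUE(global_residual)),
    class = "network_config"
  )
}

cpp_cfg <- function(cfg) {
  list(n_down = cfg$n_down, n_res = cfg$n_residual_blocks,
       base_channels = cfg$base_channels,
       use_instance_norm = cfg$use_instance_norm,
       skip_connections = cfg$skip_connections,
       global_residual = isTRUE(cfg$global_residual))
}

# Conv layer table mirroring the C++ layout: stem, downs, 2*res, ups, final.
# All convolutions are 3x3.
layer_table <- function(cfg) {
  C <- cfg$base_channels
  nd <- cfg$n_down
  nr <- cfg$n_residual_blocks
  cin <- integer(0); cout <- integer(0); has_in <- logical(0); k <- integer(0)
  add <- function(i, o, in_norm, kk = 3L) {
    cin <<- c(cin, i); cout <<- c(cout, o); has_in <<- c(has_in, in_norm)
    k <<- c(k, kk)
  }
  add(1L, C, cfg$use_instance_norm)
  ch <- C
  for (d in seq_len(nd)) { add(ch, 2L * ch, cfg$use_instance_norm); ch <- 2L * ch }
  for (r in seq_len(2L * nr)) add(ch, ch, cfg$use_instance_norm)
  for (u in seq_len(nd)) { add(ch, ch %/% 2L, cfg$use_instance_norm); ch <- ch %/% 2L }
  add(ch, 1L, FALSE)
  data.frame(cin = cin, cout = cout, has_in = has_in, k = k)
}

#' Build an untrained network
#'
#' Initialises the network parameters (He-normal convolution weights, unit
#' instance-norm gains, zero biases) deterministically from `seed`.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the weight initialisation.
#' @return a `kernel_net` object holding the parameter list.
#' @export
build_network <- function(cfg = network_config(), seed = 0) {
  if (!inherits(cfg, "network_config")) stop_param("`cfg` must be a network_config.")
  lt <- layer_table(cfg)
  params <- with_seed(seed, {
    out <- list()
    for (li in seq_len(nrow(lt))) {
      fan_in <- lt$cin[li] * lt$k[li]^2
      sd0 <- if (li == nrow(lt)) sqrt(1 / fan_in) else sqrt(2 / fan_in)
      out[[length(out) + 1L]] <- matrix(rnorm(fan_in * lt$cout[li], 0, sd0),
                                        fan_in, lt$cout[li])
      out[[length(out) + 1L]] <- numeric(lt$cout[li])
      if (lt$has_in[li]) {
        out[[length(out) + 1L]] <- rep(1, lt$cout[li])
        out[[length(out) + 1L]] <- numeric(lt$cout[li])
      }
    }
    out
  })
  structure(list(config = cfg, params = params,
                 n_parameters = n_network_parameters(cfg)),
            class = "kernel_net")
}

#' Number of trainable parameters of a configuration
#'
#' @param cfg a [network_config()].
#' @return integer parameter count.
#' @export
n_network_parameters <- function(cfg) {
  lt <- layer_table(cfg)
  sum(lt$cin * lt$k^2 * lt$cout + lt$cout + ifelse(lt$has_in, 2L * lt$cout, 0L))
}

#' HU window normaliser
#'
#' Affine map from the HU window `[window_lo, window_hi]` to the normalised
#' interval `[-1, 1]` used inside the network; values outside the window are
#' clamped first, so `denormalize_hu(normalize_hu(x))` equals
#' `clamp(x, lo, hi)`. The full model uses the window -2048..1500 HU;
#' partial models use their truncation bounds.
#'
#' @param window_lo,window_hi window bounds in HU, `window_lo < window_hi`.
#' @return a `hu_normalizer` object.
#' @export
hu_normalizer <- function(window_lo = -2048, window_hi = 1500) {
  if (!(window_lo < window_hi)) stop_param("`window_lo` must be < `window_hi`.")
  structure(list(window_lo = window_lo, window_hi = window_hi),
            class = "hu_normalizer")
}

#' @rdname hu_normalizer
#' @param x numeric array of HU values (normalised values for the inverse).
#' @param norm a `hu_normalizer`.
#' @export
normalize_hu <- function(x, norm) {
  x <- pmin(pmax(x, norm$window_lo), norm$window_hi)
  2 * (x - norm$window_lo) / (norm$window_hi - norm$window_lo) - 1
}

#' @rdname hu_normalizer
#' @export
denormalize_hu <- function(x, norm) {
  (x + 1) / 2 * (norm$window_hi - norm$window_lo) + norm$window_lo
}

#' Training configuration
#'
#' @param epochs training epochs (10 is the desk-scale default; 40 is the
#'   full-scale setting).
#' @param l1_weight,l2_weight weights of the absolute-error and
#'   squared-error terms of the loss (must not both be 0). The per-batch
#'   loss in normalised space is
#'   `l1_weight * mean|pred - target| + l2_weight * mean((pred - target)^2)`,
#'   masked to in-FOV voxels.
#' @param batch_size slices per optimisation step.
#' @param learning_rate Adam learning rate.
#' @param adam_beta1,adam_beta2 Adam moment decay rates. The second-moment
#'   decay defaults to 0.99: with small batches and short schedules the
#'   faster-adapting second moment converges more quickly than the
#'   conventional 0.999.
#' @param lr_schedule `"linear_decay"` (constant for the first half, then
#'   linear decay) or `"constant"`.
#' @param seed seed for weight init and shuffling; the whole run is
#'   bit-reproducible given this seed.
#' @param truncation optional `c(lo, hi)` HU window: both members of every
#'   training pair are clamped to it and it becomes the model's normaliser
#'   window (region-wise "partial" training).
#' @param direction `"sharp_to_soft"` (input sharp, target soft) or
#'   `"soft_to_sharp"`.
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 10, l1_weight = 1, l2_weight = 1,
                         batch_size = 2, learning_rate = 0.015,
                         adam_beta1 = 0.9, adam_beta2 = 0.99,
                         lr_schedule = c("linear_decay", "constant"),
                         seed = 0, truncation = NULL,
                         direction = c("sharp_to_soft", "soft_to_sharp")) {
  if (epochs < 1) stop_param("`epochs` must be >= 1.")
  if (l1_weight < 0 || l2_weight < 0 || l1_weight + l2_weight <= 0) {
    stop_param("loss weights must be >= 0 and not both zero.")
  }
  if (!is.null(truncation)) {
    if (length(truncation) != 2L || truncation[1] >= truncation[2]) {
      stop_param("`truncation` must be c(lo, hi) with lo < hi.")
    }
  }
  structure(
    list(epochs = as.integer(epochs), l1_weight = l1_weight,
         l2_weight = l2_weight, batch_size = as.integer(batch_size),
         learning_rate = learning_rate, adam_beta1 = adam_beta1,
         adam_beta2 = adam_beta2, lr_schedule = match.arg(lr_schedule),
         seed = as.integer(seed), truncation = truncation,
         direction = match.arg(direction)),
    class = "train_config"
  )
}

lr_per_epoch <- function(tc) {
  E <- tc$epochs
  if (tc$lr_schedule == "constant") return(rep(tc$learning_rate, E))
  h <- ceiling(E / 2)
  e <- seq_len(E)
  ifelse(e <= h, tc$learning_rate,
         tc$learning_rate * (E + 1 - e) / (E + 1 - h))
}

# reflect-pad a (n, H, W) stack on the bottom/right so H, W become multiples
# of m; returns list(arr, H0, W0)
pad_stack_to_multiple <- function(arr, m) {
  d <- dim(arr)
  H0 <- d[2]; W0 <- d[3]
  Hp <- ceiling(H0 / m) * m
  Wp <- ceiling(W0 / m) * m
  if (Hp == H0 && Wp == W0) return(list(arr = arr, H0 = H0, W0 = W0))
  if (Hp - H0 >= H0 || Wp - W0 >= W0) {
    stop_shape("slice too small to pad to the network's resolution multiple.")
  }
  ry <- c(seq_len(H0), H0:(2 * H0 - Hp + 1))[seq_len(Hp)]
  rx <- c(seq_len(W0), W0:(2 * W0 - Wp + 1))[seq_len(Wp)]
  out <- array(0, dim = c(d[1], Hp, Wp))
  for (i in seq_len(d[1])) out[i, , ] <- arr[i, , ][ry, rx]
  list(arr = out, H0 = H0, W0 = W0)
}

# (n, H, W) -> (H, W, n) cube for the C++ side
to_cube <- function(arr) aperm(arr, c(2, 3, 1))
from_cube <- function(cb) aperm(cb, c(3, 1, 2))

#' Train a kernel-conversion model
#'
#' Trains the network on matched slice pairs to minimise the combination of
#' the absolute and the squared errors between the converted slices and the
#' ground-truth slices, in normalised space, with Adam and an optional
#' linear learning-rate decay. With `truncation` set, both members of every
#' pair are clamped to that HU window first (the partial, region-wise
#' model); otherwise the model sees the full -2048..1500 HU window.
#' Outside-FOV voxels (at or below the pair set's padding value) are
#' excluded from the loss. Fully reproducible given `train_cfg$seed`.
#'
#' @param pairs a [slice_pair_set()] (at least one pair).
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @return a `kernel_model`: config, normaliser, trained parameters, and
#'   per-epoch `loss_history`.
#' @export
train_converter <- function(pairs, net_cfg = network_config(),
                            train_cfg = train_config()) {
  if (!inherits(pairs, "slice_pair_set")) stop_param("`pairs` must be a slice_pair_set.")
  n <- length(pairs)
  if (n < 1) stop_data("at least one slice pair is required for training.")
  dir <- train_cfg$direction
  input <- if (dir == "sharp_to_soft") pairs$sharp else pairs$soft
  target <- if (dir == "sharp_to_soft") pairs$soft else pairs$sharp
  mask <- (input > pairs$padding_value) * 1.0
  window <- train_cfg$truncation %||% c(-2048, 1500)
  norm <- hu_normalizer(window[1], window[2])
  input <- normalize_hu(input, norm)
  target <- normalize_hu(target, norm)
  m <- 2^net_cfg$n_down
  pin <- pad_stack_to_multiple(input, m)
  ptg <- pad_stack_to_multiple(target, m)
  pmk <- pad_stack_to_multiple(mask, m)
  # padded border is synthetic context: keep it out of the loss
  if (pin$H0 != dim(pin$arr)[2] || pin$W0 != dim(pin$arr)[3]) {
    pmk$arr[, seq_len(dim(pmk$arr)[2]) > pin$H0, ] <- 0
    pmk$arr[, , seq_len(dim(pmk$arr)[3]) > pin$W0] <- 0
  }
  net <- build_network(net_cfg, seed = train_cfg$seed)
  order <- with_seed(train_cfg$seed + 1L, {
    vapply(seq_len(train_cfg$epochs), function(e) sample.int(n), integer(n))
  })
  if (!is.matrix(order)) order <- matrix(order, nrow = n)
  fit <- cnn_train_cpp(net$params, cpp_cfg(net_cfg), to_cube(pin$arr),
                       to_cube(ptg$arr), to_cube(pmk$arr),
                       train_cfg$l1_weight, train_cfg$l2_weight,
                       train_cfg$batch_size, lr_per_epoch(train_cfg),
                       order, train_cfg$adam_beta1 %||% 0.9,
                       train_cfg$adam_beta2 %||% 0.99)
  id <- if (is.null(train_cfg$truncation)) "full" else {
    sprintf("partial[%g,%g]", window[1], window[2])
  }
  structure(
    list(config = net_cfg, normalizer = norm, params = fit$params,
         loss_history = as.numeric(fit$loss_history),
         train_config = train_cfg, id = id,
         format = "kernelconvert-model-v1"),
    class = "kernel_model"
  )
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf(
    "<kernel_model '%s'> window [%g, %g] HU, %d epochs, final loss %.4g\n",
    x$id, x$normalizer$window_lo, x$normalizer$window_hi,
    length(x$loss_history), tail_loss(x)
  ))
  invisible(x)
}

tail_loss <- function(model) model$loss_history[length(model$loss_history)]

#' Apply a trained model to a CT volume
#'
#' Slice-by-slice inference: the input is clamped to the model's HU window,
#' normalised, reflect-padded to the network's resolution multiple if
#' needed, converted, cropped back, and denormalised to HU. The bounded
#' arctan activation confines every output voxel to the model's window.
#' Outside-FOV voxels are restored to the source padding value.
#'
#' @param model a `kernel_model` (from [train_converter()]) or an untrained
#'   `kernel_net` wrapped via [untrained_model()].
#' @param vol a [ct_volume()].
#' @return a [ct_volume()] with kernel label `"converted(<model id>)"`.
#' @export
convert_volume <- function(model, vol) {
  if (!inherits(model, "kernel_model")) stop_param("`model` must be a kernel_model.")
  assert_ct_volume(vol)
  valid <- validity_mask(vol)
  x <- normalize_hu(vol$voxels, model$normalizer)
  m <- 2^model$config$n_down
  px <- pad_stack_to_multiple(x, m)
  yc <- cnn_forward_cpp(model$params, cpp_cfg(model$config), to_cube(px$arr))
  y <- from_cube(yc)[, seq_len(px$H0), seq_len(px$W0), drop = FALSE]
  out <- vol
  out$voxels <- denormalize_hu(y, model$normalizer)
  out$voxels[!valid] <- vol$padding_value
  dim(out$voxels) <- dim(vol$voxels)
  out$kernel_label <- sprintf("converted(%s)", model$id)
  out
}

#' Wrap an untrained network as a usable model
#'
#' Mainly for pipeline smoke-testing: packages freshly initialised weights
#' with a normaliser so [convert_volume()] can run without training.
#'
#' @param net a `kernel_net` from [build_network()].
#' @param norm a [hu_normalizer()].
#' @return a `kernel_model` with an empty loss history.
#' @export
untrained_model <- function(net, norm = hu_normalizer()) {
  structure(
    list(config = net$config, normalizer = norm, params = net$params,
         loss_history = numeric(0), train_config = NULL, id = "untrained",
         format = "kernelconvert-model-v1"),
    class = "kernel_model"
  )
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a single-file archive with a versioned format tag,
#' the network/normaliser configuration, and the weights.
#'
#' @param model a `kernel_model`.
#' @param path checkpoint file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "kernel_model")) stop_param("`model` must be a kernel_model.")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "kernel_model") ||
      !identical(model$format, "kernelconvert-model-v1")) {
    stop_format(sprintf("not a kernelconvert model checkpoint: %s", path))
  }
  model
}
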