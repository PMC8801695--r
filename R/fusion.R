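#' HU-dependent fusion weight specification
#'
#' Parameters of the weighted sum that merges the full-range model output
#' with the mid-range (partial) model output. In the default
#' `partial_in_middle` orientation the partial model owns the inner band
#' `[inner_lo, inner_hi]` (weight 1) and hands over to the full model across
#' linear ramps of width `ramp` HU, completing at `inner_lo - ramp` and
#' `inner_hi + ramp` (weight 0). The `verbatim` orientation reproduces the
#' printed form of the published weight expression,
#' `w = clamp(max(1 - (v + 230)/60, (v - 170)/60), 0, 1)` at the default
#' knots, which assigns the partial model to the extremes instead; it is
#' retained for exact reproduction (see the methods vignette for why the
#' middle orientation is the default).
#'
#' @param inner_lo,inner_hi inner band bounds in HU (default -170 / 170).
#' @param ramp linear ramp width in HU (default 60, > 0).
#' @param orientation `"partial_in_middle"` (default) or `"verbatim"`.
#' @param weight_source which model's output value the weight is evaluated
#'   on. The weight's job is to identify the HU regime a voxel belongs to;
#'   `"full"` (default) uses the full-range model's output, which remains a
#'   reliable regime indicator even when the partial model has not yet
#'   saturated at its window bounds, and agrees with `"partial"` (the
#'   published rule) once it has.
#' @return a `blend_spec` object.
#' @export
blend_spec <- function(inner_lo = -170, inner_hi = 170, ramp = 60,
                       orientation = c("partial_in_middle", "verbatim"),
                       weight_source = c("full", "partial")) {
  if (ramp <= 0) stop_param("`ramp` must be > 0.")
  if (!(inner_lo < inner_hi)) stop_param("`inner_lo` must be < `inner_hi`.")
  structure(list(inner_lo = inner_lo, inner_hi = inner_hi, ramp = ramp,
                 orientation = match.arg(orientation),
                 weight_source = match.arg(weight_source)),
            class = "blend_spec")
}

#' Fusion weight as a function of HU value
#'
#' Piecewise-linear, continuous weight in `[0, 1]` given to the partial
#' model's output. Vectorised over `v`.
#'
#' @param v HU value(s), typically the partial model's output.
#' @param spec a [blend_spec()].
#' @return weights in `[0, 1]`, same shape as `v`.
#' @export
#' @examples
#' blend_weight(c(-230, -200, 0, 200, 230), blend_spec())
blend_weight <- function(v, spec = blend_spec()) {
  if (!inherits(spec, "blend_spec")) stop_param("`spec` must be a blend_spec.")
  r <- spec$ramp
  w <- if (spec$orientation == "partial_in_middle") {
    pmin(pmax((v - (spec$inner_lo - r)) / r, 0),
         pmax(((spec$inner_hi + r) - v) / r, 0), 1)
  } else {
    pmax(pmin(pmax(1 - (v - (spec$inner_lo - r)) / r,
                   (v - spec$inner_hi) / r), 1), 0)
  }
  w <- pmin(pmax(w, 0), 1)
  if (!is.null(dim(v))) dim(w) <- dim(v)
  w
}

#' Fuse full-model and partial-model outputs
#'
#' Voxelwise convex combination
#' `I_final = w(v) * I_partial + (1 - w(v)) * I_full`, where the weight
#' argument `v` is the voxel's value in the image named by
#' `spec$weight_source` (the full model's output by default; the partial
#' model's output under the published rule).
#'
#' @param full_img,partial_img HU arrays of identical shape (arrays or
#'   [ct_volume()] objects).
#' @param spec a [blend_spec()].
#' @return fused HU array (or `ct_volume` if inputs were volumes).
#' @export
fuse <- function(full_img, partial_img, spec = blend_spec()) {
  as_vol <- is_ct_volume(full_img)
  fa <- if (as_vol) full_img$voxels else full_img
  pa <- if (is_ct_volume(partial_img)) partial_img$voxels else partial_img
  if (!identical(dim(fa), dim(pa))) {
    stop_shape("full and partial images must have identical shapes.")
  }
  v <- if (identical(spec$weight_source, "partial")) pa else fa
  w <- blend_weight(v, spec)
  out <- w * pa + (1 - w) * fa
  if (as_vol) {
    res <- full_img
    res$voxels <- out
    dim(res$voxels) <- dim(fa)
    res$kernel_label <- "converted(full_1_partial)"
    return(res)
  }
  out
}

#' Fuse outputs of several window-restricted models
#'
#' Each model output owns the interior of its HU window; ownership of a
#' voxel is decided by a reference estimate (the mean of the outputs whose
#' window contains the voxel's overall mean output), with linear
#' cross-fades of width `spec$ramp` across window boundaries, so the fused
#' image is continuous in the reference value and the weights sum to 1 at
#' every voxel.
#'
#' @param outputs list of `list(img = HU array, window = c(lo, hi))`; at
#'   least two entries whose windows jointly cover -2048..1500 HU with no
#'   gap wider than `spec$ramp`.
#' @param spec a [blend_spec()] (only `ramp` is used).
#' @return fused HU array.
#' @export
fuse_multi <- function(outputs, spec = blend_spec()) {
  if (length(outputs) < 2) stop_param("`fuse_multi` needs at least two outputs.")
  imgs <- lapply(outputs, function(o) {
    if (is_ct_volume(o$img)) o$img$voxels else o$img
  })
  wins <- lapply(outputs, `[[`, "window")
  d <- dim(imgs[[1]])
  for (im in imgs) {
    if (!identical(dim(im), d)) stop_shape("all outputs must share one shape.")
  }
  ord <- order(vapply(wins, `[[`, 0, 1))
  imgs <- imgs[ord]
  wins <- wins[ord]
  los <- vapply(wins, `[[`, 0, 1)
  his <- vapply(wins, `[[`, 0, 2)
  if (los[1] > -2048 || max(his) < 1500) {
    stop_param("windows must jointly cover -2048..1500 HU.")
  }
  if (length(wins) > 1) {
    gaps <- los[-1] - cummax(his)[-length(his)]
    if (any(gaps > spec$ramp)) {
      stop_param("window gaps wider than the ramp leave uncovered HU ranges.")
    }
  }
  # reference estimate: mean of the window-interior outputs at each voxel
  stack <- array(unlist(imgs, use.names = FALSE), dim = c(prod(d), length(imgs)))
  r0 <- rowMeans(stack)
  inside <- vapply(seq_along(wins), function(i) {
    r0 >= los[i] & r0 <= his[i]
  }, logical(length(r0)))
  if (!is.matrix(inside)) inside <- matrix(inside, nrow = length(r0))
  n_in <- rowSums(inside)
  ref <- ifelse(n_in > 0, rowSums(stack * inside) / pmax(n_in, 1), r0)
  # trapezoid ownership weights with ramp/2 cross-fades at each boundary
  half <- spec$ramp / 2
  glo <- min(los)
  ghi <- max(his)
  tw <- vapply(seq_along(wins), function(i) {
    lo_term <- if (los[i] <= glo) rep(Inf, length(ref)) else (ref - los[i]) / spec$ramp + 0.5
    hi_term <- if (his[i] >= ghi) rep(Inf, length(ref)) else (his[i] - ref) / spec$ramp + 0.5
    pmin(pmax(pmin(lo_term, hi_term), 0), 1)
  }, numeric(length(ref)))
  if (!is.matrix(tw)) tw <- matrix(tw, nrow = length(ref))
  tot <- rowSums(tw)
  tot[tot == 0] <- 1
  out <- rowSums(stack * tw / tot)
  array(out, dim = d)
}
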