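#' Simulation configuration for a paired-kernel study
#'
#' Study conditions for the synthetic dataset: paired sharp (0.5 mm-style,
#' double slice count) and soft (full slice spacing) reconstructions of
#' jittered thorax phantoms for a training and a validation cohort, plus
#' repeated scans of one fixed phantom. Defaults mirror the reference study
#' design: 30 training and 30 validation subjects and 6 phantom scans.
#'
#' @param n_train,n_val number of paired training / validation volumes.
#' @param shape soft-kernel volume shape `(n_slice, n_row, n_col)`; the
#'   sharp volume has `2 * n_slice` slices at half the slice spacing.
#' @param spacing_mm soft-kernel voxel spacing `(dz, dy, dx)` in mm.
#' @param params a [kernel_diff_params()].
#' @param n_phantom_scans repeated scans of the fixed phantom (>= 2).
#' @param phantom_kernel kernel used for the repeated phantom scans.
#' @param jitter relative anatomical jitter between subjects.
#' @param seed master seed; every random draw in the simulation derives
#'   from it.
#' @return a `sim_config` object.
#' @export
sim_config <- function(n_train = 30, n_val = 30, shape = c(8, 64, 64),
                       spacing_mm = c(1, 1, 1),
                       params = kernel_diff_params(),
                       n_phantom_scans = 6, phantom_kernel = "soft",
                       jitter = 0.08, seed = 0) {
  if (n_phantom_scans < 2) {
    stop_param("inter-scan variability needs at least 2 phantom scans.")
  }
  if (n_train < 1 || n_val < 1) stop_param("cohort sizes must be >= 1.")
  structure(
    list(n_train = as.integer(n_train), n_val = as.integer(n_val),
         shape = as.integer(shape), spacing_mm = as.numeric(spacing_mm),
         params = params, n_phantom_scans = as.integer(n_phantom_scans),
         phantom_kernel = phantom_kernel, jitter = jitter,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

simulate_subject <- function(config, subject_seed) {
  sd2 <- derive_seeds(subject_seed, 4)
  nr <- config$shape[2]
  nc <- config$shape[3]
  spec <- thorax_phantom_spec(nr, nc, jitter = config$jitter, seed = sd2[1])
  ns_sharp <- 2L * config$shape[1]
  sp_sharp <- c(config$spacing_mm[1] / 2, config$spacing_mm[2:3])
  ph <- make_phantom(spec, shape = c(ns_sharp, nr, nc), spacing_mm = sp_sharp,
                     seed = sd2[2])
  # soft reconstruction keeps every other slice location (origin-aligned)
  odd <- seq(1, ns_sharp, by = 2)
  truth_soft <- ct_volume(ph$volume$voxels[odd, , , drop = FALSE],
                          spacing_mm = config$spacing_mm,
                          kernel_label = "phantom", origin_mm = 0)
  sharp <- simulate_scan(ph$volume, config$params, "sharp", seed = sd2[3])
  soft <- simulate_scan(truth_soft, config$params, "soft", seed = sd2[4])
  mask_soft <- region_mask(ph$mask$labels[odd, , , drop = FALSE],
                           ph$mask$region_names)
  list(sharp = sharp, soft = soft, truth = truth_soft,
       mask = mask_soft, mask_sharp = ph$mask)
}

#' Simulate a full paired-kernel study
#'
#' Generates the training and validation cohorts and the repeated phantom
#' scans described by a [sim_config()]. Each subject is a jittered thorax
#' phantom rendered twice: a sharp-kernel volume with doubled slice count
#' at half slice spacing, and a soft-kernel volume at the nominal spacing,
#' so slice pairing mirrors the clinical 0.5 mm / 1.0 mm protocol. With
#' `out_dir` set, all volumes, masks, and a manifest (config hash and all
#' seeds) are written as NIfTI / JSON; reruns with the same config are
#' byte-identical.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return a `kernel_dataset` list: `train` and `val` (lists of subject
#'   records with `sharp`, `soft`, `truth`, `mask`), `phantom` (list with
#'   `scans` and noiseless `truth`), `config`, `manifest`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  if (!inherits(config, "sim_config")) stop_param("`config` must be a sim_config.")
  seeds <- derive_seeds(config$seed, config$n_train + config$n_val + 1L)
  train <- lapply(seq_len(config$n_train), function(i) {
    simulate_subject(config, seeds[i])
  })
  val <- lapply(seq_len(config$n_val), function(i) {
    simulate_subject(config, seeds[config$n_train + i])
  })
  nr <- config$shape[2]
  nc <- config$shape[3]
  ph <- make_phantom(thorax_phantom_spec(nr, nc), shape = config$shape,
                     spacing_mm = config$spacing_mm,
                     seed = seeds[config$n_train + config$n_val + 1L])
  scans <- repeated_scans(ph$volume, config$params, config$phantom_kernel,
                          n = config$n_phantom_scans,
                          seed = seeds[config$n_train + config$n_val + 1L])
  manifest <- list(
    package_version = as.character(utils::packageVersion("kernelconvert")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    subject_seeds = seeds
  )
  ds <- structure(
    list(train = train, val = val,
         phantom = list(scans = scans, truth = ph$volume, mask = ph$mask),
         config = config, manifest = manifest),
    class = "kernel_dataset"
  )
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort <- function(cohort, tag) {
    for (i in seq_along(cohort)) {
      base <- file.path(out_dir, sprintf("%s_%03d", tag, i))
      write_volume(cohort[[i]]$sharp, paste0(base, "_sharp.nii.gz"))
      write_volume(cohort[[i]]$soft, paste0(base, "_soft.nii.gz"))
      write_volume(cohort[[i]]$mask, paste0(base, "_mask.nii.gz"),
                   spacing_mm = cohort[[i]]$soft$spacing_mm)
    }
  }
  write_cohort(ds$train, "train")
  write_cohort(ds$val, "val")
  for (i in seq_along(ds$phantom$scans)) {
    write_volume(ds$phantom$scans[[i]],
                 file.path(out_dir, sprintf("phantom_scan_%02d.nii.gz", i)))
  }
  write_volume(ds$phantom$truth, file.path(out_dir, "phantom_truth.nii.gz"))
  jsonlite::write_json(ds$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.kernel_dataset <- function(x, ...) {
  cat(sprintf(
    "<kernel_dataset> %d training + %d validation paired volumes, %d phantom scans\n",
    length(x$train), length(x$val), length(x$phantom$scans)
  ))
  invisible(x)
}

dataset_pairs <- function(cohort, direction = "sharp_to_soft") {
  sets <- lapply(seq_along(cohort), function(i) {
    ps <- pair_slices(cohort[[i]]$sharp, cohort[[i]]$soft)
    ps$source_id <- sprintf("subject_%03d", i)
    ps
  })
  bind_pairs(sets)
}

#' Train the full + partial model bundle
#'
#' Trains the full-range model (no truncation) and the mid-range partial
#' model (-300..300 HU) on the training cohort's slice pairs; with
#' `three_partial = TRUE` also trains the low (-2048..0) and high (0..1500)
#' partial models for the 3-partial variant. The conversion direction
#' (sharp-to-soft by default, or the reverse) is taken from `train_cfg`.
#'
#' @param dataset a `kernel_dataset` from [simulate_dataset()], or any list
#'   with a `train` cohort of `sharp`/`soft` volume pairs.
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()]; its `truncation` field is managed
#'   per model and ignored here.
#' @param blend a [blend_spec()] stored in the bundle.
#' @param partial_learning_rate learning rate for the window-truncated
#'   models (default 0.01). Narrow windows magnify errors and gradients in
#'   normalised units, so the partial models train more stably at a lower
#'   rate than the full-range model.
#' @param partial_global_residual use the global identity path also in the
#'   partial models (default `FALSE`). Inside a narrow window the identity
#'   path feeds the input's amplified noise straight to the output, which
#'   costs mid-band accuracy, while the level-anchoring it provides matters
#'   mainly across the full HU range.
#' @param three_partial also train the -2048..0 and 0..1500 models.
#' @param out_file optional path; the bundle (checkpoints + blend spec) is
#'   saved there via [save_bundle()].
#' @return a `conversion_bundle`.
#' @export
train_pipeline <- function(dataset, net_cfg = network_config(base_channels = 8),
                           train_cfg = train_config(), blend = blend_spec(),
                           partial_learning_rate = 0.01,
                           partial_global_residual = FALSE,
                           three_partial = FALSE, out_file = NULL) {
  if (is.null(dataset$train) || !length(dataset$train)) {
    stop_data("dataset has no training volumes.")
  }
  pairs <- dataset_pairs(dataset$train)
  cfg_for <- function(truncation) {
    tc <- train_cfg
    tc$truncation <- truncation
    if (!is.null(truncation)) tc$learning_rate <- partial_learning_rate
    tc
  }
  part_net <- net_cfg
  part_net$global_residual <- isTRUE(partial_global_residual)
  models <- list(
    full = train_converter(pairs, net_cfg, cfg_for(NULL)),
    partial_mid = train_converter(pairs, part_net, cfg_for(c(-300, 300)))
  )
  if (three_partial) {
    models$partial_lo <- train_converter(pairs, part_net, cfg_for(c(-2048, 0)))
    models$partial_hi <- train_converter(pairs, part_net, cfg_for(c(0, 1500)))
  }
  bundle <- structure(
    list(models = models, blend = blend, direction = train_cfg$direction,
         net_config = net_cfg, train_config = train_cfg,
         manifest = list(
           package_version = as.character(utils::packageVersion("kernelconvert")),
           train_config_hash = rlang::hash(unclass(train_cfg)),
           seed = train_cfg$seed
         ),
         format = "kernelconvert-bundle-v1"),
    class = "conversion_bundle"
  )
  if (!is.null(out_file)) save_bundle(bundle, out_file)
  bundle
}

#' @export
print.conversion_bundle <- function(x, ...) {
  cat(sprintf("<conversion_bundle> %s; models: %s\n", x$direction,
              paste(names(x$models), collapse = ", ")))
  invisible(x)
}

#' Save / load a conversion bundle
#'
#' @param bundle a `conversion_bundle`.
#' @param path bundle file path.
#' @return `save_bundle` returns `path` invisibly; `load_bundle` the bundle.
#' @export
save_bundle <- function(bundle, path) {
  if (!inherits(bundle, "conversion_bundle")) {
    stop_param("`bundle` must be a conversion_bundle.")
  }
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  b <- readRDS(path)
  if (!inherits(b, "conversion_bundle") ||
      !identical(b$format, "kernelconvert-bundle-v1")) {
    stop_format(sprintf("not a kernelconvert bundle: %s", path))
  }
  b
}

#' Convert a volume with a trained bundle
#'
#' @param bundle a `conversion_bundle`.
#' @param vol the input [ct_volume()] (sharp-kernel for the default
#'   direction).
#' @param variant `"full_1_partial"` (full + mid-range partial fused by the
#'   HU-dependent weight; default), `"full"` (full model only), or
#'   `"three_partial"` (window-ownership fusion of the three partial
#'   models; needs a bundle trained with `three_partial = TRUE`).
#' @return converted [ct_volume()].
#' @export
convert_with_bundle <- function(bundle, vol,
                                variant = c("full_1_partial", "full",
                                            "three_partial")) {
  variant <- match.arg(variant)
  if (variant == "full") return(convert_volume(bundle$models$full, vol))
  if (variant == "full_1_partial") {
    full <- convert_volume(bundle$models$full, vol)
    part <- convert_volume(bundle$models$partial_mid, vol)
    return(fuse(full, part, bundle$blend))
  }
  need <- c("partial_lo", "partial_mid", "partial_hi")
  if (!all(need %in% names(bundle$models))) {
    stop_data("bundle lacks the three partial models; train with three_partial = TRUE.")
  }
  outs <- list(
    list(img = convert_volume(bundle$models$partial_lo, vol), window = c(-2048, 0)),
    list(img = convert_volume(bundle$models$partial_mid, vol), window = c(-300, 300)),
    list(img = convert_volume(bundle$models$partial_hi, vol), window = c(0, 1500))
  )
  out <- vol
  out$voxels <- fuse_multi(outs, bundle$blend)
  dim(out$voxels) <- dim(vol$voxels)
  out$voxels[!validity_mask(vol)] <- vol$padding_value
  out$kernel_label <- "converted(three_partial)"
  out
}

standard_masks <- function(mask) {
  list(
    lung = as_binary_mask(mask, c("lung_left", "lung_right",
                                  "emphysema_left", "emphysema_right")),
    muscle = as_binary_mask(mask, c("muscle_left", "muscle_right")),
    coronary = as_binary_mask(mask, "calcification")
  )
}

#' Run the full validation report
#'
#' Applies every conversion method to each validation subject and compiles
#' the complete report: per-band error summaries for the raw sharp volume,
#' the full-model conversion, the fused full-1-partial conversion, the
#' 3-partial conversion (when the bundle has it), the calibrated Gaussian
#' and median filter baselines, and a ground-truth sanity channel; phantom
#' inter-scan variability with per-band acceptability verdicts; Dice
#' coefficients of low-attenuation masks; LAV%, IMAT% and CAC Bland-Altman
#' agreement; and Bonferroni-corrected paired t-tests of the Dice scores.
#'
#' @param bundle a trained `conversion_bundle`.
#' @param dataset a `kernel_dataset` with `val` volumes and phantom scans.
#' @param bands band table as from [default_hu_bands()].
#' @param pool `"per_volume"` (default: per-subject band summaries, pooled
#'   across subjects by pooling their voxel differences) or `"pooled"`
#'   (all subjects' voxels pooled before summarising); both are computed
#'   from pooled voxel differences over the cohort, the flag controls
#'   whether per-subject summaries are also returned.
#' @return a `validation_report` list of tibbles.
#' @export
run_validation <- function(bundle, dataset, bands = default_hu_bands(),
                           pool = c("per_volume", "pooled")) {
  pool <- match.arg(pool)
  if (is.null(dataset$val) || !length(dataset$val)) {
    stop_data("dataset has no validation volumes.")
  }
  if (is.null(dataset$phantom) || length(dataset$phantom$scans) < 2) {
    stop_data("dataset has no repeated phantom scans.")
  }
  train_pairs <- dataset_pairs(dataset$train)
  sp <- dataset$train[[1]]$sharp$spacing_mm[2:3]
  gcal <- calibrate_filter(train_pairs, "gaussian", spacing_mm = sp)
  mcal <- calibrate_filter(train_pairs, "median")

  methods <- list(
    sharp = function(sub) resample_to_soft(sub),
    full_dnn = function(sub) convert_with_bundle(bundle, sub$sharp, "full") |>
      subset_to_soft(sub),
    full_1_partial = function(sub) convert_with_bundle(bundle, sub$sharp,
                                                       "full_1_partial") |>
      subset_to_soft(sub),
    gaussian = function(sub) gaussian_convert(sub$sharp, gcal$parameter) |>
      subset_to_soft(sub),
    median = function(sub) median_convert(sub$sharp, mcal$parameter) |>
      subset_to_soft(sub),
    ground_truth = function(sub) sub$soft
  )
  if (all(c("partial_lo", "partial_hi") %in% names(bundle$models))) {
    methods$three_partial <- function(sub) {
      convert_with_bundle(bundle, sub$sharp, "three_partial") |>
        subset_to_soft(sub)
    }
  }

  method_names <- names(methods)
  diff_pool <- setNames(vector("list", length(methods)), method_names)
  ref_pool <- NULL
  per_sub <- lapply(dataset$val, function(sub) {
    ref <- sub$soft
    masks <- standard_masks(sub$mask)
    lav_ref_mask <- low_attenuation_mask(ref, masks$lung)
    res <- lapply(method_names, function(mn) {
      conv <- methods[[mn]](sub)
      diffs <- band_errors(conv, ref, bands)
      valid <- validity_mask(conv) & validity_mask(ref)
      diff_pool[[mn]] <<- c(diff_pool[[mn]],
                            conv$voxels[valid] - ref$voxels[valid])
      if (mn == method_names[1]) {
        ref_pool <<- c(ref_pool, ref$voxels[valid])
      }
      qr <- dplyr::bind_rows(
        lav_percent(conv, masks$lung),
        imat_percent(conv, masks$muscle),
        cac_volume(conv, masks$coronary)
      )
      list(
        method = mn,
        diffs = dplyr::mutate(diffs, method = mn),
        dice = dice(low_attenuation_mask(conv, masks$lung), lav_ref_mask),
        quant = dplyr::mutate(qr, method = mn)
      )
    })
    ref_quant <- dplyr::bind_rows(
      lav_percent(ref, masks$lung),
      imat_percent(ref, masks$muscle),
      cac_volume(ref, masks$coronary)
    )
    list(res = res, ref_quant = ref_quant)
  })

  # pooled band errors per method (voxel differences pooled over subjects;
  # band membership by the pooled reference values, identical per method)
  pooled_bands <- purrr::map_dfr(method_names, function(mn) {
    out <- purrr::pmap_dfr(bands, function(name, lo, hi) {
      sel <- ref_pool >= lo & ref_pool < hi
      summarize_band(name, lo, hi, diff_pool[[mn]][sel])
    })
    dplyr::mutate(out, method = mn)
  })
  phantom_var <- interscan_variability(dataset$phantom$scans, bands)
  verdicts <- compare_to_phantom(
    dplyr::filter(pooled_bands, .data$method == "full_1_partial") |>
      dplyr::select(-"method"),
    dplyr::filter(phantom_var, .data$band != "all"),
    factor = 1.5
  )
  dice_tbl <- purrr::map_dfr(seq_along(per_sub), function(i) {
    purrr::map_dfr(per_sub[[i]]$res, function(r) {
      tibble(subject = i, method = r$method, dice = r$dice)
    })
  })
  quant_tbl <- purrr::map_dfr(seq_along(per_sub), function(i) {
    dplyr::bind_rows(
      purrr::map_dfr(per_sub[[i]]$res, `[[`, "quant"),
      dplyr::mutate(per_sub[[i]]$ref_quant, method = "soft_reference")
    ) |> dplyr::mutate(subject = i)
  })
  ba <- quant_bland_altman(quant_tbl, method = "full_1_partial")
  dice_wide <- split(dice_tbl$dice, dice_tbl$method)
  # the comparison set of the Dice analysis: fused conversion against the
  # Gaussian-filtered, median-filtered, and raw sharp images
  competitors <- dice_wide[intersect(c("gaussian", "median", "sharp"),
                                     names(dice_wide))]
  m_comp <- length(competitors)
  tests <- purrr::map_dfr(names(competitors), function(nm) {
    tryCatch(
      paired_t_bonferroni(dice_wide$full_1_partial, competitors[nm],
                          m = m_comp),
      error = function(e) {
        # degenerate or too-short comparison: reported as NA, not dropped
        tibble(comparison = nm, statistic = NA_real_, df = NA_real_,
               p_raw = NA_real_, p_adjusted = NA_real_)
      }
    )
  })
  structure(
    list(band_errors = pooled_bands, phantom = phantom_var,
         verdicts = verdicts, dice = dice_tbl, quantification = quant_tbl,
         bland_altman = ba, dice_tests = tests,
         filter_parameters = tibble(kind = c("gaussian", "median"),
                                    parameter = c(gcal$parameter,
                                                  mcal$parameter)),
         pool = pool),
    class = "validation_report"
  )
}

# sharp volumes carry twice the slices; reduce to the soft grid by taking
# the slice nearest each soft location
resample_to_soft <- function(sub) {
  ps <- pair_slices(sub$sharp, sub$soft)
  ct_volume(ps$sharp, spacing_mm = sub$soft$spacing_mm,
            kernel_label = sub$sharp$kernel_label,
            padding_value = sub$sharp$padding_value,
            origin_mm = sub$soft$origin_mm)
}

subset_to_soft <- function(conv, sub) {
  ps <- pair_slices(conv, sub$soft)
  ct_volume(ps$sharp, spacing_mm = sub$soft$spacing_mm,
            kernel_label = conv$kernel_label,
            padding_value = conv$padding_value,
            origin_mm = sub$soft$origin_mm)
}

quant_bland_altman <- function(quant_tbl, method) {
  purrr::map_dfr(unique(quant_tbl$index_name), function(idx) {
    ref <- dplyr::filter(quant_tbl, .data$index_name == idx,
                         .data$method == "soft_reference")
    tst <- dplyr::filter(quant_tbl, .data$index_name == idx,
                         .data$method == !!method)
    ba <- bland_altman(tst$value[order(tst$subject)],
                       ref$value[order(ref$subject)])
    tibble(index_name = idx, method = method, bias = ba$bias,
           loa_lo = ba$loa_lo, loa_hi = ba$loa_hi, n = ba$n)
  })
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  methods:", paste(unique(x$band_errors$method), collapse = ", "), "\n")
  cat(sprintf("  %d Dice rows, %d quantification rows\n",
              nrow(x$dice), nrow(x$quantification)))
  invisible(x)
}

#' Write a validation report to CSV/JSON files
#'
#' @param report a `validation_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$band_errors,
                   file.path(out_dir, "band_errors.csv"), row.names = FALSE)
  utils::write.csv(report$phantom,
                   file.path(out_dir, "phantom_variability.csv"),
                   row.names = FALSE)
  utils::write.csv(report$dice, file.path(out_dir, "dice.csv"),
                   row.names = FALSE)
  utils::write.csv(report$quantification,
                   file.path(out_dir, "quantification.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(bland_altman = report$bland_altman, verdicts = report$verdicts,
         dice_tests = report$dice_tests,
         filter_parameters = report$filter_parameters),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(out_dir)
}
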