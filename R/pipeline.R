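# Run configuration and the end-to-end pipeline:
# normalize -> derive masks -> train -> predict -> postprocess -> evaluate.

#' Default run configuration
#'
#' Nested configuration covering every stage; serialized as YAML by
#' [save_config()]/[load_config()]. Defaults are desk-scale (reduced
#' network, 128 px synthetic tiles) so a full run fits on one CPU.
#'
#' @param seed global seed; every stage derives its own stream from it.
#' @return a nested `run_config` list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    log_level = "info",
    stain = list(enabled = TRUE, sparsity_weight = 0.1, tissue_threshold = 0.15),
    masks = list(contour_thickness = 2, white_threshold = 220),
    synth = list(n_train = 200, n_test = 20, tile_size = 128, n_glands = 4,
                 gland_radius_min = 14, gland_radius_max = 28,
                 lumen_fraction = 0.2, noise_sd = 3),
    model = list(block_layers = c(2, 2, 2, 2), growth_rate = 8,
                 input_size = 128, decoder_channels = c(64, 32, 16, 16, 8),
                 init_channels = 16),
    train = list(lr = 1e-3, beta1 = 0.90, beta2 = 0.99, batch_size = 4,
                 epochs = 5, steps_per_epoch = 10, plateau_patience = 5,
                 lr_factor = 0.5, val_fraction = 0.2, alpha = 0.5,
                 weight_decay = 1e-4, noise_sd = 5),
    postprocess = list(t_object = 0.5, t_contour = 0.5, dilation_iters = 2,
                       min_area_frac = 0.00087, crf_iters = 5, use_crf = TRUE),
    metrics = list(hausdorff = "symmetric")
  ), class = "run_config")
}

check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stopf("unknown config key(s): %s", paste0(path, extra, collapse = ", "))
  for (nm in names(cfg))
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(path, nm, "."))
  invisible(TRUE)
}

#' Load / save a run configuration as YAML
#'
#' Unknown keys are rejected; missing keys fall back to defaults.
#'
#' @param path YAML file path.
#' @return a `run_config` (`load_config`); `path` invisibly (`save_config`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- default_config()
  check_config_keys(raw, ref)
  merge_cfg <- function(ref, new) {
    for (nm in names(new)) {
      ref[[nm]] <- if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])))
        merge_cfg(ref[[nm]], new[[nm]]) else new[[nm]]
    }
    ref
  }
  cfg <- merge_cfg(unclass(ref), raw)
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param config a `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_line <- function(con, level, fmt, ...) {
  msg <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                 level, sprintf(fmt, ...))
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

cfg_to_model <- function(m) {
  model_config(block_layers = m$block_layers, growth_rate = m$growth_rate,
               input_size = m$input_size, decoder_channels = m$decoder_channels,
               init_channels = m$init_channels)
}

cfg_to_postprocess <- function(cfg) {
  area <- cfg$model$input_size^2
  postprocess_config(
    t_object = cfg$postprocess$t_object, t_contour = cfg$postprocess$t_contour,
    dilation_iters = cfg$postprocess$dilation_iters,
    min_area = max(1L, round(cfg$postprocess$min_area_frac * area)),
    crf_iters = cfg$postprocess$crf_iters,
    white_threshold = cfg$masks$white_threshold,
    use_crf = cfg$postprocess$use_crf)
}

#' Run the full segmentation pipeline
#'
#' Executes the whole chain on synthetic tissue (or a user manifest):
#' dataset generation, stain normalization to the first training tile,
#' training of the chosen route, prediction and post-processing on the test
#' tiles, and Dice/Hausdorff evaluation. Every stage writes under
#' `out_dir`, including the resolved configuration and a log; the global
#' seed makes the run reproducible end to end.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param approach `"gland"` or `"stroma"`.
#' @param out_dir run directory (created).
#' @param manifest optional training manifest (data.frame or CSV path) of
#'   real tiles; `NULL` generates synthetic data per `config$synth`.
#' @param test_manifest optional held-out manifest when `manifest` is given.
#' @return a `glandseg_run`: list with `eval` (a `gland_eval`), `model`,
#'   `pred_dir`, `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), approach = c("gland", "stroma"),
                         out_dir, manifest = NULL, test_manifest = NULL) {
  approach <- match.arg(approach)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_config(config, file.path(out_dir, "config.yaml"))
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  stage <- function(name, expr) {
    log_line(logf, "info", "stage %s: start", name)
    r <- tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
    log_line(logf, "info", "stage %s: done", name)
    r
  }
  seed <- config$seed
  if (is.null(manifest)) {
    synth_dir <- file.path(out_dir, "synth")
    ds <- stage("synth", {
      sp <- synth_params(tile_size = config$synth$tile_size,
                         n_glands = config$synth$n_glands,
                         gland_radius_range = c(config$synth$gland_radius_min,
                                                config$synth$gland_radius_max),
                         lumen_fraction = config$synth$lumen_fraction,
                         noise_sd = config$synth$noise_sd,
                         seed = derive_seed(seed, "synth"))
      n_total <- config$synth$n_train + config$synth$n_test
      generate_dataset(sp, n_total, synth_dir)
    })
    manifest <- ds[seq_len(config$synth$n_train), ]
    test_manifest <- ds[config$synth$n_train + seq_len(config$synth$n_test), ]
  } else {
    manifest <- load_manifest(manifest)
    if (is.null(test_manifest)) stopf("data error: test_manifest required")
    test_manifest <- load_manifest(test_manifest)
  }
  if (config$stain$enabled) {
    norm_dir <- file.path(out_dir, "normalized")
    manifest <- stage("normalize", {
      dir.create(norm_dir, showWarnings = FALSE)
      target_tile <- read_image(manifest$image[1])
      tgt <- stain_target(target_tile, seed = derive_seed(seed, "stain"),
                          sparsity_weight = config$stain$sparsity_weight,
                          tissue_threshold = config$stain$tissue_threshold)
      norm_one <- function(df) {
        df$image <- vapply(seq_len(nrow(df)), function(i) {
          out <- file.path(norm_dir, basename(df$image[i]))
          img <- normalize_image(read_image(df$image[i]), tgt$basis, tgt$scale,
                                 seed = derive_seed(seed, df$image[i]),
                                 sparsity_weight = config$stain$sparsity_weight,
                                 tissue_threshold = config$stain$tissue_threshold)
          write_image(img, out)
          out
        }, character(1))
        df
      }
      test_manifest <- norm_one(test_manifest)
      norm_one(manifest)
    })
  }
  model <- stage("train", {
    train_model(manifest, approach,
                model_cfg = cfg_to_model(config$model),
                train_cfg = train_config(
                  lr = config$train$lr,
                  betas = c(config$train$beta1, config$train$beta2),
                  batch_size = config$train$batch_size,
                  epochs = config$train$epochs,
                  steps_per_epoch = config$train$steps_per_epoch,
                  plateau_patience = config$train$plateau_patience,
                  lr_factor = config$train$lr_factor,
                  val_fraction = config$train$val_fraction,
                  seed = derive_seed(seed, paste0("train-", approach))),
                loss_cfg = loss_config(config$train$alpha,
                                       config$train$weight_decay),
                contour_thickness = config$masks$contour_thickness,
                white_threshold = config$masks$white_threshold,
                noise_sd = config$train$noise_sd)
  })
  utils::write.csv(model$history, file.path(out_dir, paste0("history_", approach, ".csv")),
                   row.names = FALSE)
  save_model(model, file.path(out_dir, paste0("model_", approach, ".rds")))
  pp <- cfg_to_postprocess(config)
  pred_dir <- file.path(out_dir, paste0("pred_", approach))
  truth_dir <- file.path(out_dir, "truth")
  stage("predict", {
    dir.create(pred_dir, showWarnings = FALSE)
    dir.create(truth_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(test_manifest))) {
      tile <- resize_raster(read_image(test_manifest$image[i]),
                            config$model$input_size)
      inst <- resize_raster(read_mask(test_manifest$annotation[i]) * 1.0,
                            config$model$input_size, "nearest")
      maps <- predict_maps(model, tile)
      seg <- segment_glands(maps, tile, approach, pp)
      id <- tools::file_path_sans_ext(basename(test_manifest$image[i]))
      write_mask(seg, file.path(pred_dir, paste0(id, ".tif")))
      write_mask(matrix(as.integer(inst > 0), nrow(inst), ncol(inst)),
                 file.path(truth_dir, paste0(id, ".tif")))
    }
  })
  ev <- stage("evaluate", {
    evaluate_dataset(pred_dir, truth_dir,
                     out_csv = file.path(out_dir, paste0("report_", approach, ".csv")),
                     hausdorff = config$metrics$hausdorff)
  })
  log_line(logf, "info", "mean dice %.4f, mean hausdorff %.2f px",
           ev$mean_dice, ev$mean_hausdorff)
  structure(list(eval = ev, model = model, pred_dir = pred_dir,
                 truth_dir = truth_dir, out_dir = out_dir),
            class = "glandseg_run")
}
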