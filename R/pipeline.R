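default_run_config <- function() {
  list(
    output_dir = "graftunet_run",
    data = list(synthetic = NULL, images_dir = NULL, masks_dir = NULL),
    split = list(train_fraction = 0.7, seed = 1L),
    preprocess = list(enabled = FALSE, alpha = 50, s_max = 4,
                      tiles = 8L, mode = "lab"),
    arch = list(input_size = 64L, filter_depths = c(8L, 16L, 32L, 48L, 64L),
                se = FALSE, upsample = "nearest"),
    train = list(epochs = 40L, batch_size = 4L, learning_rate = 1e-4,
                 loss = "bce", seed = 1L),
    evaluate = list(threshold = 0.5),
    overlays = 4L
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

in_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Evaluate prediction PNGs against ground-truth masks on disk
#'
#' Pairs the two folders by filename, reads predictions as probability
#' maps (first channel) and ground truths as binary masks, and runs
#' [evaluate_set()]. This makes any written report recomputable from the
#' persisted artefacts alone.
#'
#' @param pred_dir,gt_dir Folders of identically named PNGs.
#' @param threshold Binarisation threshold.
#' @param aggregation Primary aggregation mode of the report.
#' @return A `metric_report`.
#' @export
evaluate_dirs <- function(pred_dir, gt_dir, threshold = 0.5,
                          aggregation = c("per_image_mean", "global_counts")) {
  idx <- index_dataset(pred_dir, gt_dir)
  preds <- lapply(idx$image, function(p) read_frame(p)[, , 1L])
  gts <- lapply(idx$mask, read_mask)
  evaluate_set(preds, gts, threshold = threshold,
               aggregation = match.arg(aggregation))
}

#' Run a full experiment from a configuration
#'
#' Executes the whole pipeline: synthetic data generation (or indexing
#' of an existing paired-folder dataset), optional CLAHE preprocessing,
#' a seeded train/test split, training, prediction on the test split,
#' evaluation under both aggregation modes, and contour overlays. All
#' artefacts (report JSON, prediction PNGs, overlay PNGs, model
#' checkpoint) are written under `output_dir`.
#'
#' @param config Path to a YAML configuration file, or an equivalent
#'   named list. Unspecified fields fall back to defaults (64x64 input,
#'   70/30 split, 40 epochs, batch 4, Adam at 1e-4, BCE loss).
#' @return An object of class `run_report` (invisibly): the evaluation
#'   report, per-epoch losses, configuration echo and per-stage timings.
#' @export
run_experiment <- function(config) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- merge_config(default_run_config(), user)
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t_all <- tic()

  t0 <- tic()
  idx <- in_stage("data", {
    if (!is.null(cfg$data$synthetic)) {
      scfg <- do.call(synthetic_config, cfg$data$synthetic)
      generate_dataset(scfg, file.path(out, "data", "images"),
                       file.path(out, "data", "masks"))
    } else {
      if (is.null(cfg$data$images_dir) || is.null(cfg$data$masks_dir))
        stop("config needs data$synthetic or data$images_dir + data$masks_dir")
      index_dataset(cfg$data$images_dir, cfg$data$masks_dir)
    }
  })
  timings["data"] <- tic() - t0

  if (isTRUE(cfg$preprocess$enabled)) {
    t0 <- tic()
    idx <- in_stage("preprocess", {
      pp <- clahe_params(tiles_x = cfg$preprocess$tiles,
                         tiles_y = cfg$preprocess$tiles,
                         alpha = cfg$preprocess$alpha,
                         s_max = cfg$preprocess$s_max)
      pdir <- file.path(out, "preprocessed")
      n <- preprocess_dataset(dirname(idx$image[1]), pdir, pp,
                              mode = cfg$preprocess$mode)
      message("preprocessed ", n, " frames")
      index_dataset(pdir, dirname(idx$mask[1]))
    })
    timings["preprocess"] <- tic() - t0
  }

  t0 <- tic()
  parts <- in_stage("split",
    split_dataset(idx, cfg$split$train_fraction, cfg$split$seed))
  timings["split"] <- tic() - t0

  s <- as.integer(cfg$arch$input_size)
  arch <- in_stage("arch",
    arch_config(input_h = s, input_w = s,
                filter_depths = cfg$arch$filter_depths,
                se_enabled = isTRUE(cfg$arch$se),
                upsample = cfg$arch$upsample))
  tcfg <- train_config(epochs = cfg$train$epochs,
                       batch_size = cfg$train$batch_size,
                       learning_rate = cfg$train$learning_rate,
                       loss = cfg$train$loss, seed = cfg$train$seed)

  t0 <- tic()
  fit <- in_stage("train",
    train(parts$train, arch, tcfg,
          checkpoint = file.path(out, "model.rds")))
  timings["train"] <- tic() - t0

  t0 <- tic()
  test_pairs <- as.data.frame(parts$test)
  preds <- in_stage("predict", {
    loaded <- lapply(seq_len(nrow(test_pairs)), function(i)
      load_and_resize(test_pairs[i, ], s, s))
    frames <- lapply(loaded, `[[`, "image")
    list(maps = predict(fit$model, frames), loaded = loaded)
  })
  timings["predict"] <- tic() - t0

  t0 <- tic()
  report <- in_stage("evaluate", {
    gts <- lapply(preds$loaded, `[[`, "mask")
    pred_dir <- file.path(out, "predictions")
    dir.create(pred_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(test_pairs)))
      write_frame(preds$maps[[i]], file.path(pred_dir, test_pairs$name[i]))
    gt_dir <- file.path(out, "test_masks")
    dir.create(gt_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(test_pairs)))
      write_frame(gts[[i]], file.path(gt_dir, test_pairs$name[i]))
    evaluate_set(preds$maps, gts, threshold = cfg$evaluate$threshold)
  })
  timings["evaluate"] <- tic() - t0

  t0 <- tic()
  in_stage("overlay", {
    odir <- file.path(out, "overlays")
    dir.create(odir, showWarnings = FALSE)
    k <- min(cfg$overlays, nrow(test_pairs))
    for (i in seq_len(k)) {
      ov <- render_overlay(preds$loaded[[i]]$image,
                           preds$loaded[[i]]$mask,
                           (preds$maps[[i]] >= cfg$evaluate$threshold) * 1)
      write_frame(ov, file.path(odir, test_pairs$name[i]))
    }
  })
  timings["overlay"] <- tic() - t0

  run <- structure(list(
    metrics = list(per_image_mean = as.list(report$per_image_mean),
                   global_counts = as.list(report$global_counts)),
    counts = unclass(report$counts)[c("tp", "fp", "fn", "tn")],
    threshold = cfg$evaluate$threshold,
    n_train = nrow(as.data.frame(parts$train)),
    n_test = nrow(test_pairs),
    per_epoch_loss = fit$report$per_epoch_loss,
    config = cfg,
    timings_sec = as.list(timings),
    wall_clock_sec = tic() - t_all), class = "run_report")
  jsonlite::write_json(unclass(run), file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Graft-U-Net run:", x$n_train, "train /", x$n_test, "test frames\n")
  cat("final training loss:",
      format(tail_loss <- x$per_epoch_loss[length(x$per_epoch_loss)],
             digits = 5), "\n")
  cat("test metrics (per-image mean):\n")
  print(round(unlist(x$metrics$per_image_mean), 4))
  invisible(x)
}
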