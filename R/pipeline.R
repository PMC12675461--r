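# One entry point wiring the modules into the full workflow:
# generate phantoms -> split -> train -> evaluate -> explain. Driven by a
# schema-validated YAML configuration whose keys mirror the model's
# hyperparameter names; every stage writes its outputs under the run
# directory, and a resumed run skips stages whose outputs already exist.

pipeline_schema <- list(
  seed = NULL, out_dir = NULL, stages = NULL,
  phantom = c("n_tumor", "n_healthy", "image_size", "lesion_radius_range",
    "lesion_intensity_range", "brain_axes_range", "noise_sd",
    "brightness_jitter", "channel_mode", "format"),
  split = c("ratios", "paper_mode"),
  augment = c("rotation_range", "width_shift_range", "height_shift_range",
    "shear_range", "zoom_range", "horizontal_flip", "fill_mode"),
  edge = c("filter_type", "trainable_filters", "conv_filters"),
  se = c("ratio"),
  model = c("img_size", "backbone", "pretrained_weights", "fine_tune_at",
    "dense_units", "dropout_rate", "num_classes", "learning_rate", "epochs",
    "batch_size", "steps_per_epoch", "early_stop", "lr_plateau"),
  xai = c("methods", "n_examples", "n_segments", "n_samples", "top_k")
)

#' Validate a pipeline configuration
#'
#' Rejects unknown sections or keys and checks cross-field constraints
#' (ratio sums, positive counts) before any I/O happens.
#'
#' @param config A list (typically parsed from YAML).
#' @return The config, invisibly, on success; otherwise an error.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown)) {
    abort(sprintf("Unknown config section(s): %s.", paste(unknown, collapse = ", ")),
      class = "sobelnet_error_validation")
  }
  for (sec in names(config)) {
    allowed <- pipeline_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad)) {
      abort(sprintf("Unknown key(s) in section '%s': %s.", sec, paste(bad, collapse = ", ")),
        class = "sobelnet_error_validation")
    }
  }
  if (!is.null(config$split$ratios) && sum(unlist(config$split$ratios)) > 1 + 1e-9) {
    abort("Split ratios must sum to at most 1.", class = "sobelnet_error_validation")
  }
  invisible(config)
}

default_run_config <- function() {
  list(
    seed = 42L,
    phantom = list(n_tumor = 164L, n_healthy = 136L, image_size = 64L,
      format = "png"),
    split = list(ratios = c(0.7, 0.15, 0.15), paper_mode = FALSE),
    augment = list(),
    edge = list(conv_filters = 32L),
    se = list(ratio = 16L),
    model = list(img_size = 64L, dense_units = 1024L, dropout_rate = 0.5,
      learning_rate = 1e-3, epochs = 15L, batch_size = 16L),
    xai = list(methods = c("saliency", "gradcam", "gradcampp", "lime"),
      n_examples = 4L, n_segments = 40L, n_samples = 150L, top_k = 5L)
  )
}

log_line <- function(run_dir, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(...))
  message(msg)
  cat(msg, "\n", file = file.path(run_dir, "run.log"), append = TRUE)
}

stage_done <- function(run_dir, stage) {
  file.exists(file.path(run_dir, paste0(".done_", stage)))
}

mark_done <- function(run_dir, stage) {
  writeLines(format(Sys.time()), file.path(run_dir, paste0(".done_", stage)))
}

#' Run the full workflow
#'
#' Stages, in order: `generate` (phantom dataset), `split`, `train`,
#' `evaluate`, `explain`. The resolved configuration is written to the run
#' directory as a reproducibility record, a log is kept in `run.log`, and
#' with `resume = TRUE` completed stages are skipped.
#'
#' @param config Path to a YAML config file, or a config list. Omitted keys
#'   fall back to desk-scale defaults.
#' @param out_dir Run directory (default: `out_dir` from the config, else a
#'   temporary directory).
#' @param resume Skip stages whose outputs already exist?
#' @param verbose Log epoch-by-epoch training progress?
#' @return The run directory path, invisibly; outputs inside: the dataset
#'   and split manifests, `history.tsv`, `weights.rds`, `metrics.json`,
#'   and one overlay PNG per requested attribution method.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, resume = FALSE,
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  cfg <- modifyList(default_run_config(), config)
  run_dir <- out_dir %||% cfg$out_dir %||% file.path(tempdir(), "sobelnet_run")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(run_dir, "resolved_config.yaml"))

  seed <- as.integer(cfg$seed)
  data_dir <- file.path(run_dir, "dataset")
  split_dir <- file.path(run_dir, "split")

  # -- generate --------------------------------------------------------------
  if (!(resume && stage_done(run_dir, "generate"))) {
    log_line(run_dir, "stage generate: %d tumor + %d healthy phantoms",
      cfg$phantom$n_tumor, cfg$phantom$n_healthy)
    pcfg_args <- cfg$phantom[setdiff(names(cfg$phantom), c("n_tumor", "n_healthy", "format"))]
    pcfg <- do.call(phantom_config, c(pcfg_args, list(seed = seed)))
    generate_dataset(cfg$phantom$n_tumor, cfg$phantom$n_healthy, data_dir,
      pcfg, format = cfg$phantom$format %||% "png")
    mark_done(run_dir, "generate")
  }

  # -- split -----------------------------------------------------------------
  if (!(resume && stage_done(run_dir, "split"))) {
    log_line(run_dir, "stage split: ratios %s", paste(unlist(cfg$split$ratios), collapse = "/"))
    spec <- split_spec(ratios = unlist(cfg$split$ratios), seed = seed,
      source = data_dir, target = split_dir,
      paper_mode = isTRUE(cfg$split$paper_mode))
    manifest <- split_dataset(spec)
    viol <- verify_split(manifest)
    if (nrow(viol) > 0L && !isTRUE(cfg$split$paper_mode)) {
      abort("Split verification reported violations.", class = "sobelnet_error_validation")
    }
    mark_done(run_dir, "split")
  }
  manifest <- as_tibble(utils::read.delim(file.path(split_dir, "split_manifest.tsv"),
    colClasses = "character"))
  attr(manifest, "target") <- split_dir

  img_size <- cfg$model$img_size
  ranges <- do.call(augment_ranges, cfg$augment)
  mcfg <- do.call(model_config, c(cfg$model, list(seed = seed)))
  ecfg <- do.call(edge_config, cfg$edge)
  scfg <- se_config(ratio = cfg$se$ratio %||% 16L)
  classes <- sort(unique(manifest$class), method = "radix")

  # -- train -----------------------------------------------------------------
  weights_path <- file.path(run_dir, "weights.rds")
  if (!(resume && stage_done(run_dir, "train"))) {
    log_line(run_dir, "stage train: %d epochs, lr %g", mcfg$epochs, mcfg$learning_rate)
    train_stream <- make_stream(manifest, "train", "train", mcfg$batch_size,
      img_size, seed = seed, ranges = ranges)
    val_stream <- make_stream(manifest, "val", "eval", mcfg$batch_size,
      img_size, seed = seed)
    model <- build_model(mcfg, ecfg, scfg, classes = classes)
    model <- train_model(model, train_stream, val_stream, verbose = verbose)
    save_model_weights(model, weights_path)
    utils::write.table(model$history, file.path(run_dir, "history.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    mark_done(run_dir, "train")
  } else {
    model <- build_model(mcfg, ecfg, scfg, classes = classes)
    model <- load_model_weights(model, weights_path)
  }

  # -- evaluate --------------------------------------------------------------
  if (!(resume && stage_done(run_dir, "evaluate"))) {
    log_line(run_dir, "stage evaluate")
    test_stream <- make_stream(manifest, "test", "eval", mcfg$batch_size,
      img_size, seed = seed)
    ev <- eval_pass(model, test_stream)
    probs <- ev$probs
    colnames(probs) <- model$classes
    truth <- model$classes[ev$labels]
    report <- metrics_report(truth, probs)
    write_metrics_report(report, file.path(run_dir, "metrics.json"))
    roc <- dplyr::bind_rows(report$roc)
    utils::write.table(roc, file.path(run_dir, "roc.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    mark_done(run_dir, "evaluate")
  }

  # -- explain ---------------------------------------------------------------
  if (!(resume && stage_done(run_dir, "explain"))) {
    log_line(run_dir, "stage explain: %s", paste(cfg$xai$methods, collapse = ", "))
    tumor_cls <- if ("tumor" %in% classes) "tumor" else tail(classes, 1)
    tum <- manifest[manifest$subset == "test" & manifest$class == tumor_cls, ]
    n_ex <- min(cfg$xai$n_examples %||% 4L, nrow(tum))
    for (i in seq_len(n_ex)) {
      path <- file.path(split_dir, "test", tumor_cls, tum$file[i])
      raw <- ensure_rgb(resize_bilinear(unclass(read_image(path)), img_size, img_size))
      norm <- raw / 127.5 - 1
      for (method in cfg$xai$methods) {
        map <- switch(method,
          saliency = minmax_norm(unclass(vanilla_saliency(model, norm, tumor_cls))),
          gradcam = unclass(grad_cam(model, norm, tumor_cls)),
          gradcampp = unclass(grad_cam_pp(model, norm, tumor_cls)),
          lime = {
            ex <- lime_explain(model, norm, tumor_cls,
              n_segments = cfg$xai$n_segments %||% 40L,
              n_samples = cfg$xai$n_samples %||% 150L,
              k = cfg$xai$top_k %||% 5L, seed = seed)
            ex$top_k_mask * 1
          },
          abort(sprintf("Unknown attribution method '%s'.", method),
            class = "sobelnet_error_validation"))
        render_overlay(image_array(raw, "raw"), map,
          file.path(run_dir, sprintf("overlay_%s_%02d.png", method, i)))
      }
    }
    mark_done(run_dir, "explain")
  }
  log_line(run_dir, "pipeline complete")
  invisible(run_dir)
}

#' Package and backend version information
#'
#' @return Character vector (also printed): package version, compute
#'   backend, and the seeding policy.
#' @export
version_info <- function() {
  lines <- c(
    sprintf("sobelnet %s", as.character(utils::packageVersion("sobelnet"))),
    sprintf("backend: base-R reference engine (BLAS matmul), R %s",
      paste(R.version$major, R.version$minor, sep = ".")),
    "seed policy: one integer seed drives phantom generation, splitting, augmentation, initialization, and dropout"
  )
  cat(lines, sep = "\n")
  invisible(lines)
}
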