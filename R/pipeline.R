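# End-to-end orchestration: ingest -> mask -> grid -> features ->
# classify -> vote -> report.

#' Pipeline configuration
#'
#' Bundles every tunable of the detection pipeline. The defaults are the
#' preferred operating point established by the parameter study:
#' 80 x 80 blocks, LBP(8, 1), LBP + RGB features, RBF SVM with C = 64 and
#' gamma = 1, medium (75%) ROI mask.
#'
#' @param block_size Grid block side, pixels.
#' @param lbp_p,lbp_r LBP sampling points and radius.
#' @param combination Feature combination id (see
#'   [combination_colorspaces()]).
#' @param C,gamma SVM parameters.
#' @param mask_scale ROI ellipse scale fraction.
#' @param width,height Working resolution (inputs are resized to this).
#' @param seed Integer seed for any stochastic pipeline step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(block_size = 80, lbp_p = 8, lbp_r = 1,
                            combination = "lbp_rgb", C = 64, gamma = 1,
                            mask_scale = 0.75, width = 960, height = 720,
                            seed = 1) {
  check_lbp_config(lbp_p, lbp_r)
  combination <- match.arg(tolower(combination), names(FEATURE_COMBINATIONS))
  cfg <- list(block_size = block_size, lbp_p = lbp_p, lbp_r = lbp_r,
              combination = combination, C = C, gamma = gamma,
              mask_scale = mask_scale, width = width, height = height,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_config: block %dx%d, LBP(%d, %d), %s, ",
                     "SVM C = %g gamma = %g, mask %.2f, seed %d>\n"),
              x$block_size, x$block_size, x$lbp_p, x$lbp_r, x$combination,
              x$C, x$gamma, x$mask_scale, x$seed))
  invisible(x)
}

config_mask <- function(config) {
  ellipse_mask(config$width, config$height, config$mask_scale)
}

log_stage <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(...)))
}

#' Per-block features for one image
#'
#' Resizes to the working resolution if needed, applies the ROI mask and
#' extracts the configured block features.
#'
#' @param image Array `c(H, W, 3)` 0-255, or a `synth_beef` object.
#' @param config A [pipeline_config()].
#' @return Tibble from [block_features()].
#' @export
extract_image_features <- function(image, config = pipeline_config()) {
  if (inherits(image, "synth_beef")) image <- image$image
  image <- resize_image(image, config$width, config$height)
  mask <- config_mask(config)
  blocks <- valid_blocks(mask, config$block_size)
  block_features(image, blocks, combination = config$combination,
                 P = config$lbp_p, R = config$lbp_r)
}

#' Streamed feature extraction over a dataset manifest
#'
#' Renders each manifest image in turn (optionally perturbed), extracts
#' its block features and discards the pixels, so memory stays flat for
#' arbitrarily large datasets.
#'
#' @param dataset A [generate_dataset()] manifest.
#' @param config A [pipeline_config()].
#' @param splits Optional character vector restricting which splits are
#'   processed (e.g. `c("train", "test")`).
#' @param image_ids Optional vector of `image_id`s to restrict to.
#' @param perturb Optional function `function(image, image_seed)` applied
#'   to each rendered image before feature extraction (used for the
#'   robustness sweeps).
#' @param progress Print a progress message every 100 images.
#' @return Tibble: `image_id`, `class`, `split`, `block_id`, `x`, `y`,
#'   feature columns.
#' @export
extract_dataset_features <- function(dataset, config = pipeline_config(),
                                     splits = NULL, perturb = NULL,
                                     image_ids = NULL, progress = FALSE) {
  rows <- if (is.null(splits)) dataset else dataset[dataset$split %in% splits, ]
  if (!is.null(image_ids)) rows <- rows[rows$image_id %in% image_ids, ]
  mask <- config_mask(config)
  blocks <- valid_blocks(mask, config$block_size)
  specs <- attr(dataset, "specs") %||% default_phenotypes()
  out <- purrr::imap(seq_len(nrow(rows)), function(i, ...) {
    r <- rows[i, ]
    sb <- synth_image(specs[[as.character(r$class)]], r$image_seed,
                      mask = attr(dataset, "mask") %||% mask)
    img <- sb$image
    if (!is.null(perturb)) img <- perturb(img, r$image_seed)
    feats <- block_features(img, blocks, combination = config$combination,
                            P = config$lbp_p, R = config$lbp_r)
    if (progress && i %% 100 == 0) log_stage("features: %d/%d images", i,
                                             nrow(rows))
    dplyr::bind_cols(tibble(image_id = r$image_id, class = r$class,
                            split = r$split), feats)
  })
  dplyr::bind_rows(out)
}

#' Fit the block classifier on the training split
#'
#' @param features Feature tibble from [extract_dataset_features()].
#' @param config A [pipeline_config()].
#' @return A [marble_svm()] model (scaler fitted on the training split
#'   only).
#' @export
fit_pipeline <- function(features, config = pipeline_config()) {
  train <- features[features$split == "train", ]
  if (nrow(train) == 0) abort("no training rows in features")
  fc <- feature_columns(train)
  marble_svm(as.matrix(train[, fc]), train$class,
             C = config$C, gamma = config$gamma)
}

#' Block predictions for a feature tibble
#'
#' @param model A `marble_svm`.
#' @param features Feature tibble.
#' @return The tibble with a `.pred` factor column appended.
#' @export
predict_blocks <- function(model, features) {
  fc <- feature_columns(features)
  dplyr::mutate(features, .pred = predict(model, as.matrix(features[, fc])))
}

#' Image-level labels by majority vote over block predictions
#'
#' @param block_preds Output of [predict_blocks()] (needs `image_id`,
#'   `.pred`, and `class` if present).
#' @return Tibble: `image_id`, (`class`,) `.pred`, `tie`.
#' @export
vote_images <- function(block_preds) {
  grp <- dplyr::group_by(block_preds, .data$image_id)
  out <- dplyr::summarise(
    grp,
    class = if ("class" %in% names(block_preds)) .data$class[1] else NULL,
    .pred = vote_image(.data$.pred)$final,
    tie = vote_image(.data$.pred)$tie,
    .groups = "drop")
  out
}

#' Evaluate the pipeline on a feature tibble
#'
#' Predicts every block, aggregates to image labels by priority-tie-break
#' majority vote, and computes block- and image-level metrics.
#'
#' @param model A `marble_svm`.
#' @param features Feature tibble with truth `class` (typically the test
#'   split).
#' @param config Configuration echoed into the report.
#' @return An object of class `marble_eval`: `block_metrics`,
#'   `image_metrics` (both `marble_metrics`), `block_predictions`,
#'   `image_predictions`, `config`.
#' @export
evaluate_pipeline <- function(model, features, config = NULL) {
  bp <- predict_blocks(model, features)
  ip <- vote_images(bp)
  structure(
    list(block_metrics = block_metrics(bp$.pred, bp$class),
         image_metrics = image_metrics(ip$.pred, ip$class),
         block_predictions = bp[, c("image_id", "class", "block_id", ".pred")],
         image_predictions = ip,
         config = config,
         config_hash = if (!is.null(config)) rlang::hash(config) else NULL),
    class = "marble_eval")
}

#' @export
print.marble_eval <- function(x, ...) {
  cat("Block level:\n"); print(x$block_metrics)
  cat("Image level:\n"); print(x$image_metrics)
  invisible(x)
}

#' @rdname evaluate_pipeline
#' @param x A `marble_eval`.
#' @param ... Unused.
#' @export
glance.marble_eval <- function(x, ...) {
  dplyr::bind_rows(glance(x$block_metrics), glance(x$image_metrics))
}

#' Classify a single image
#'
#' @param model A `marble_svm`.
#' @param image Image array, `synth_beef`, or a PNG/JPEG path.
#' @param config A [pipeline_config()].
#' @return List: `label` (factor), `vote` (`marble_vote`), `blocks`
#'   (tibble with per-block `.pred`).
#' @export
classify_image <- function(model, image, config = pipeline_config()) {
  if (is.character(image)) image <- read_beef_image(image)
  feats <- extract_image_features(image, config)
  fc <- feature_columns(feats)
  preds <- predict(model, as.matrix(feats[, fc]))
  v <- vote_image(preds)
  list(label = v$final, vote = v,
       blocks = dplyr::mutate(feats[, c("block_id", "x", "y")],
                              size = config$block_size, .pred = preds))
}

#' Run one stage of the detection workflow
#'
#' Thin orchestration over the package functions, mirroring the stages of
#' the detection system: `simulate` writes a synthetic dataset to disk,
#' `extract` computes feature CSVs, `train` fits and saves a model
#' (optionally grid-searching C and gamma), `evaluate` writes block- and
#' image-level metric JSON, `predict` classifies one image. Used by the
#' command-line wrapper in `inst/cli/marblesense.R`.
#'
#' @param command One of `"simulate"`, `"extract"`, `"train"`,
#'   `"evaluate"`, `"predict"`.
#' @param config A [pipeline_config()].
#' @param paths Named list of input/output locations; which entries are
#'   used depends on the command: `data_dir` (simulate/extract),
#'   `features` (extract/train/evaluate), `model`
#'   (train/evaluate/predict), `metrics` (evaluate), `image`, `out`
#'   (predict), `grid` (train, optional: run grid search and export the
#'   CSV).
#' @param n_per_class Dataset size for `simulate`.
#' @return Command-dependent artifact, invisibly (dataset manifest,
#'   feature tibble, model, `marble_eval`, or classification list).
#' @export
run_pipeline <- function(command = c("simulate", "extract", "train",
                                     "evaluate", "predict"),
                         config = pipeline_config(), paths = list(),
                         n_per_class = 200) {
  command <- match.arg(command)
  log_stage("stage %s start (config %s)", command, rlang::hash(unclass(config)))
  res <- switch(
    command,
    simulate = {
      d <- generate_dataset(n_per_class, seed = config$seed,
                            mask = config_mask(config))
      write_dataset(d, paths$data_dir)
      d
    },
    extract = {
      d <- read_manifest(paths$data_dir)
      f <- extract_dataset_features(d, config, progress = TRUE)
      write.csv(f, paths$features, row.names = FALSE)
      f
    },
    train = {
      f <- read_features(paths$features)
      if (!is.null(paths$grid)) {
        tr <- f[f$split == "train", ]; va <- f[f$split == "validation", ]
        fc <- feature_columns(f)
        g <- grid_search(as.matrix(tr[, fc]), tr$class,
                         as.matrix(va[, fc]), va$class)
        write_grid_table(g, paths$grid)
        log_stage("grid search best (C, gamma) = (%g, %g)", g$best_C,
                  g$best_gamma)
        save_model(g$best_model, paths$model)
        g$best_model
      } else {
        m <- fit_pipeline(f, config)
        save_model(m, paths$model)
        m
      }
    },
    evaluate = {
      if (is.null(paths$model) || !file.exists(paths$model)) {
        abort("evaluate requires a trained model file")
      }
      m <- load_model(paths$model)
      f <- read_features(paths$features)
      ev <- evaluate_pipeline(m, f[f$split == "test", ], config = config)
      if (!is.null(paths$metrics)) {
        write_metrics(ev$block_metrics,
                      sub("\\.json$", "_block.json", paths$metrics),
                      config = unclass(config))
        write_metrics(ev$image_metrics,
                      sub("\\.json$", "_image.json", paths$metrics),
                      config = unclass(config))
      }
      ev
    },
    predict = {
      if (is.null(paths$model) || !file.exists(paths$model)) {
        abort("predict requires a trained model file")
      }
      m <- load_model(paths$model)
      cl <- classify_image(m, paths$image, config)
      log_stage("image %s -> %s", paths$image, as.character(cl$label))
      if (!is.null(paths$out)) {
        write.csv(cl$blocks, paths$out, row.names = FALSE)
      }
      cl
    })
  log_stage("stage %s end", command)
  invisible(res)
}

read_manifest <- function(data_dir) {
  m <- read.csv(file.path(data_dir, "manifest.csv"))
  d <- as_tibble(m)
  d$class <- beef_class(d$class)
  structure(d, class = c("marble_dataset", class(tibble())),
            specs = default_phenotypes(), mask = ellipse_mask())
}

read_features <- function(path) {
  f <- as_tibble(read.csv(path))
  f$class <- beef_class(f$class)
  f
}
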