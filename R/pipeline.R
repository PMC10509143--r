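#' Split a dataset manifest into training and testing groups
#'
#' Shuffles the rows once under `seed` and takes the first
#' `floor(ratio * n)` as the training group, the remainder as the testing
#' group (so 851 records at the default 7:3 ratio give 595 / 256). The two
#' groups partition the manifest: no overlap, nothing dropped.
#'
#' @param manifest data.frame of records (one per image).
#' @param ratio training fraction, strictly between 0 and 1 (default 0.7).
#' @param seed RNG seed for the shuffle.
#' @return List with `train` and `test` data.frames.
#' @export
split_dataset <- function(manifest, ratio = 0.7, seed = 1L) {
  manifest <- as.data.frame(manifest)
  n <- nrow(manifest)
  if (n < 1L) stop("`manifest` is empty", call. = FALSE)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("`ratio` must be strictly between 0 and 1", call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(ratio * n)
  list(train = manifest[perm[seq_len(n_train)], , drop = FALSE],
       test = manifest[perm[setdiff(seq_len(n), seq_len(n_train))], ,
                       drop = FALSE])
}

#' Balanced k-fold assignment
#'
#' Shuffles once under `seed` and deals indices round-robin, so fold sizes
#' differ by at most one (n = 11, k = 5 gives sizes 3,2,2,2,2).
#'
#' @param n number of observations.
#' @param k number of folds (`2 <= k <= n`).
#' @param seed RNG seed.
#' @return Integer vector of fold labels (1..k), length n.
#' @export
kfold_indices <- function(n, k = 5L, seed = 1L) {
  if (k < 2L) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("cannot make %d folds from %d observations", k, n),
                  call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  fold
}

# One uniform surface over the three predictor families used by the
# experiment driver, cross-validation and batch prediction.
fit_pipeline_model <- function(model_name, images, masses, config,
                               background_color, sponge_base_color) {
  if (model_name == "feature_extraction") {
    feats <- extract_features_batch(images, background_color,
                                    sponge_base_color)
    fit <- fit_hb_linear(feats, masses)
    list(name = model_name, fit = fit,
         background_color = background_color,
         sponge_base_color = sponge_base_color)
  } else {
    kind <- if (model_name == "se_resnet") "se_resnet" else "resnet"
    crops <- lapply(images, function(im) {
      px <- if (inherits(im, "synthetic_image")) im$pixels else im
      crop(px, detect_sponge_region(px, background_color))
    })
    model <- build_regressor(kind, config)
    fit <- train_hb_cnn(model, crops, masses)
    list(name = model_name, fit = fit,
         background_color = background_color,
         sponge_base_color = sponge_base_color)
  }
}

predict_pipeline_model <- function(pm, images, clamp = FALSE) {
  crops <- lapply(images, function(im) {
    px <- if (inherits(im, "synthetic_image")) im$pixels else im
    crop(px, detect_sponge_region(px, pm$background_color))
  })
  if (pm$name == "feature_extraction") {
    feats <- as.data.frame(do.call(rbind, lapply(
      crops, extract_features, pm$sponge_base_color)))
    predict(pm$fit, feats, clamp = clamp)
  } else {
    predict(pm$fit, crops, clamp = clamp)
  }
}

#' Experiment configuration
#'
#' Bundles every knob of an end-to-end run: synthetic dataset size and
#' ranges, scene, 7:3 split ratio, the models to fit, the CNN configuration
#' and the master seed. Serialisable to/from YAML via
#' [read_experiment_config()].
#'
#' @param n number of synthetic images.
#' @param models character vector among `"feature_extraction"`, `"resnet"`,
#'   `"se_resnet"`.
#' @param split_ratio training fraction (default 0.7).
#' @param concentration_range,volume_range sampling ranges (g/L, mL).
#' @param scene a [scene_params()].
#' @param regressor a [regressor_config()] for the CNN models.
#' @param seed master seed (dataset, split and model seeds derive from it).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(n = 200L,
                              models = "feature_extraction",
                              split_ratio = 0.7,
                              concentration_range = c(50, 170),
                              volume_range = c(1.0, 2.0),
                              scene = scene_params(),
                              regressor = regressor_config(variant = "tiny"),
                              seed = 1L) {
  known <- c("feature_extraction", "resnet", "se_resnet")
  if (length(models) < 1L || !all(models %in% known)) {
    stop("`models` must be a non-empty subset of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (split_ratio <= 0 || split_ratio >= 1) {
    stop("`split_ratio` must be strictly between 0 and 1", call. = FALSE)
  }
  structure(list(n = as.integer(n), models = models,
                 split_ratio = split_ratio,
                 concentration_range = concentration_range,
                 volume_range = volume_range, scene = scene,
                 regressor = regressor, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Recognised top-level keys mirror the [experiment_config()] arguments;
#' `scene` and `regressor` may be nested maps of the corresponding
#' constructor arguments.
#'
#' @param path YAML file.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare `n:` key as boolean FALSE; accept either spelling
  n_images <- y$n_images %||% y[["n"]] %||% y[["FALSE"]]
  scene <- if (is.null(y$scene)) scene_params() else
    do.call(scene_params, y$scene)
  regressor <- if (is.null(y$regressor)) regressor_config(variant = "tiny")
  else do.call(regressor_config, y$regressor)
  experiment_config(
    n = n_images %||% 200L,
    models = unlist(y$models %||% "feature_extraction"),
    split_ratio = y$split_ratio %||% 0.7,
    concentration_range = unlist(y$concentration_range %||% c(50, 170)),
    volume_range = unlist(y$volume_range %||% c(1.0, 2.0)),
    scene = scene, regressor = regressor, seed = y$seed %||% 1L)
}

#' Run an end-to-end Hb-loss estimation experiment
#'
#' Generates (or accepts) a synthetic dataset, splits it 7:3, fits every
#' requested model on the training group (detect, crop, then features +
#' OLS or CNN), predicts the testing group, and reports per model a
#' [metric_set()] and a [bland_altman()] analysis (both computed on the
#' raw, unclamped predictions) plus the pairwise improvement table.
#' When `outdir` is given, writes per-model prediction CSVs, a
#' performance table (`algorithm, mae_mg, mape_pct, r2`), an agreement
#' table (bias/LOA with CIs) and a JSON summary; reruns with an identical
#' config produce byte-identical summaries.
#'
#' @param config an [experiment_config()].
#' @param outdir optional output directory for CSV/JSON artefacts.
#' @param data optional precomputed result of [simulate_sponges()]; when
#'   omitted the dataset is generated from `config`.
#' @return Object of class `hb_experiment`.
#' @export
run_experiment <- function(config, outdir = NULL, data = NULL) {
  if (!inherits(config, "experiment_config")) {
    stop("`config` must be an experiment_config", call. = FALSE)
  }
  if (is.null(data)) {
    data <- simulate_sponges(config$n, config$concentration_range,
                             config$volume_range, config$scene, config$seed)
  }
  manifest <- data$manifest
  manifest$index <- seq_len(nrow(manifest))
  sp <- split_dataset(manifest, config$split_ratio, config$seed + 1L)
  train_imgs <- data$images[sp$train$index]
  test_imgs <- data$images[sp$test$index]
  y_train <- sp$train$hb_mass_mg
  y_test <- sp$test$hb_mass_mg

  models <- list()
  metrics <- list()
  agreements <- list()
  predictions <- list()
  for (mn in config$models) {
    reg_cfg <- config$regressor
    reg_cfg$seed <- config$seed + match(mn, config$models)
    pm <- fit_pipeline_model(mn, train_imgs, y_train, reg_cfg,
                             config$scene$background_color,
                             config$scene$sponge_base_color)
    raw <- predict_pipeline_model(pm, test_imgs, clamp = FALSE)
    models[[mn]] <- pm
    metrics[[mn]] <- metric_set(y_test, raw)
    agreements[[mn]] <- bland_altman(raw, y_test)
    predictions[[mn]] <- data.frame(
      filename = sp$test$filename,
      actual_mg = y_test,
      predicted_raw_mg = raw,
      predicted_mg = pmax(raw, 0),
      stringsAsFactors = FALSE)
  }
  improvements <- if (length(metrics) >= 2L) compare_models(metrics) else NULL

  report <- structure(
    list(config = config, models = models, metrics = metrics,
         agreements = agreements, predictions = predictions,
         improvements = improvements,
         n_train = nrow(sp$train), n_test = nrow(sp$test)),
    class = "hb_experiment")
  if (!is.null(outdir)) write_experiment_report(report, outdir)
  report
}

write_experiment_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  perf <- data.frame(
    algorithm = names(report$metrics),
    mae_mg = vapply(report$metrics, `[[`, numeric(1), "mae"),
    mape_pct = vapply(report$metrics, `[[`, numeric(1), "mape"),
    r2 = vapply(report$metrics, `[[`, numeric(1), "r2"),
    row.names = NULL, stringsAsFactors = FALSE)
  utils::write.csv(perf, file.path(outdir, "performance.csv"),
                   row.names = FALSE, quote = FALSE)
  agr <- do.call(rbind, lapply(names(report$agreements), function(mn) {
    a <- report$agreements[[mn]]
    data.frame(algorithm = mn, bias = a$bias,
               bias_ci_lo = a$ci_bias[1], bias_ci_hi = a$ci_bias[2],
               loa_lower = a$loa_lower,
               loa_lower_ci_lo = a$ci_loa_lower[1],
               loa_lower_ci_hi = a$ci_loa_lower[2],
               loa_upper = a$loa_upper,
               loa_upper_ci_lo = a$ci_loa_upper[1],
               loa_upper_ci_hi = a$ci_loa_upper[2],
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(agr, file.path(outdir, "agreement.csv"),
                   row.names = FALSE, quote = FALSE)
  for (mn in names(report$predictions)) {
    utils::write.csv(report$predictions[[mn]],
                     file.path(outdir, paste0("predictions_", mn, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  summary <- list(
    seed = report$config$seed,
    n = report$config$n,
    n_train = report$n_train,
    n_test = report$n_test,
    models = lapply(report$metrics, function(m) {
      list(mae_mg = m$mae, mape_pct = m$mape, r2 = m$r2)
    }),
    agreement = lapply(report$agreements, function(a) {
      list(bias_mg = a$bias, loa_lower_mg = a$loa_lower,
           loa_upper_mg = a$loa_upper)
    }),
    improvements = report$improvements
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.hb_experiment <- function(x, ...) {
  cat(sprintf("Hb-loss experiment: %d images (%d train / %d test)\n",
              x$config$n, x$n_train, x$n_test))
  for (mn in names(x$metrics)) {
    cat(sprintf("  %-20s ", mn)); print(x$metrics[[mn]])
  }
  invisible(x)
}

#' k-fold cross-validation of a predictor family
#'
#' Shuffles once, partitions into k near-equal folds, trains the requested
#' model on k-1 folds and evaluates on the held-out fold, for each fold in
#' turn.
#'
#' @param images list of images (or `synthetic_image` objects).
#' @param masses true Hb masses (mg).
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param model one of `"feature_extraction"`, `"resnet"`, `"se_resnet"`.
#' @param config [regressor_config()] for the CNN models.
#' @param background_color,sponge_base_color scene colours for detection and
#'   segmentation.
#' @return Object of class `hb_kfold`: per-fold `metrics` and `agreement`,
#'   the fold assignment, and mean/SD of MAE, MAPE and R^2 across folds.
#' @export
kfold_cv <- function(images, masses, k = 5L, seed = 1L,
                     model = "feature_extraction",
                     config = regressor_config(variant = "tiny"),
                     background_color = scene_params()$background_color,
                     sponge_base_color = scene_params()$sponge_base_color) {
  n <- length(images)
  fold <- kfold_indices(n, k, seed)
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    pm <- fit_pipeline_model(model, images[tr], masses[tr], config,
                             background_color, sponge_base_color)
    raw <- predict_pipeline_model(pm, images[te], clamp = FALSE)
    folds[[f]] <- list(metrics = metric_set(masses[te], raw),
                       agreement = bland_altman(raw, masses[te]),
                       test_indices = te)
  }
  stat <- function(field) vapply(folds, function(f) f$metrics[[field]],
                                 numeric(1))
  structure(list(
    folds = folds, fold_id = fold, k = k, model = model,
    mean = c(mae = mean(stat("mae")), mape = mean(stat("mape")),
             r2 = mean(stat("r2"))),
    sd = c(mae = stats::sd(stat("mae")), mape = stats::sd(stat("mape")),
           r2 = stats::sd(stat("r2")))),
    class = "hb_kfold")
}

#' @export
print.hb_kfold <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of %s\n", x$k, x$model))
  cat(sprintf("  MAE  %.4g +/- %.4g mg\n", x$mean["mae"], x$sd["mae"]))
  cat(sprintf("  MAPE %.4g +/- %.4g %%\n", x$mean["mape"], x$sd["mape"]))
  cat(sprintf("  R^2  %.4g +/- %.4g\n", x$mean["r2"], x$sd["r2"]))
  invisible(x)
}

#' Batch prediction and total Hb loss
#'
#' Mirrors the interactive use case: a stack of sponge photographs is
#' uploaded, each is detected, cropped and predicted, and the running total
#' of (clamped) predicted Hb loss is reported. Unreadable files are skipped
#' with a warning and listed in the result.
#'
#' @param paths character vector of PNG image paths, or a list of in-memory
#'   H x W x 3 arrays.
#' @param model a fitted pipeline model: an `hb_linear` (predictions go
#'   through feature extraction) or a trained `hb_cnn`.
#' @param background_color,sponge_base_color scene colours for detection and
#'   segmentation.
#' @return Object of class `batch_prediction`: `predictions` data.frame
#'   (`source`, `hb_mass_mg`), `count`, `total_mg` and `skipped`.
#' @export
predict_batch <- function(paths, model,
                          background_color = scene_params()$background_color,
                          sponge_base_color = scene_params()$sponge_base_color) {
  load_one <- function(p) {
    if (is.character(p)) {
      tryCatch(png::readPNG(p), error = function(e) NULL)
    } else if (inherits(p, "synthetic_image")) p$pixels else p
  }
  labels <- if (is.character(paths)) paths else
    sprintf("image_%d", seq_along(paths))
  items <- if (is.character(paths)) as.list(paths) else paths
  images <- lapply(items, load_one)
  bad <- vapply(images, is.null, logical(1))
  if (length(items) > 0L && all(bad)) {
    stop("no readable image among the inputs", call. = FALSE)
  }
  if (any(bad)) {
    warning(sprintf("skipped %d unreadable image(s): %s", sum(bad),
                    paste(labels[bad], collapse = ", ")), call. = FALSE)
  }
  keep <- which(!bad)
  preds <- numeric(0)
  if (length(keep) > 0L) {
    pm <- list(name = if (inherits(model, "hb_linear")) "feature_extraction"
               else "cnn",
               fit = model, background_color = background_color,
               sponge_base_color = sponge_base_color)
    preds <- predict_pipeline_model(pm, images[keep], clamp = TRUE)
  }
  structure(list(
    predictions = data.frame(source = labels[keep], hb_mass_mg = preds,
                             stringsAsFactors = FALSE),
    count = length(keep),
    total_mg = sum(preds),
    skipped = labels[bad]),
    class = "batch_prediction")
}

#' @export
print.batch_prediction <- function(x, ...) {
  cat(sprintf("Batch prediction: %d image(s), total Hb loss %.4g mg\n",
              x$count, x$total_mg))
  if (length(x$skipped) > 0L) {
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
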