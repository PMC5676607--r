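# Whole-scene deployment of a trained model and the end-to-end pipeline:
# simulate -> features -> balance/split -> fit -> evaluate -> map, driven
# by a schema-validated configuration and one master seed.

# ---- configuration ----------------------------------------------------------

#' Default run configuration
#'
#' Nested list consumed by [run_pipeline()] and the CLI. The scene block
#' carries the synthetic-generator conditions (see [scene_params()]);
#' `sampling` the survey-polygon counts and size; `features` the texture
#' window, feature subset and whether inputs are standardized; `split` the
#' calibration fraction; `train` the [train_config()] fields; `output` the
#' artifact directory and raster formats.
#'
#' @param seed Master seed recorded in the config.
#' @return Nested named list, class `"mlpard_config"`.
#' @export
default_config <- function(seed = 0L) {
  structure(list(
    seed = as.integer(seed),
    scene = list(height = 256L, width = 256L, patch_scale = 40,
                 coverage_fraction = 0.4, pixel_size = 0.5,
                 green_mean = c(0.13, 0.12), red_mean = c(0.10, 0.11),
                 nir_mean = c(0.55, 0.30),
                 noise_sd = c(0.02, 0.02, 0.03), noise_scale = 5,
                 texture_contrast = 0.08),
    sampling = list(n_target = 17L, n_other = 13L, rect_height = 6L,
                    rect_width = 6L),
    features = list(window_size = 7L, standardize = TRUE,
                    use = c("green", "red", "nir", "texture")),
    split = list(train_fraction = 0.7),
    train = list(hidden_count = 8L, inner_iterations = 100L,
                 outer_cycles = 10L, alpha_init = 0.01, alpha_max = 1e6,
                 alpha_tol = 1e-3),
    output = list(dir = NULL, write_tiff = FALSE, write_png = FALSE)
  ), class = "mlpard_config")
}

#' Validate a run configuration against the schema
#'
#' Unknown keys at any level are rejected; missing keys are filled from
#' [default_config()]; basic range checks are applied.
#'
#' @param config Nested list (e.g. parsed from YAML).
#' @return The merged, validated `"mlpard_config"`.
#' @export
validate_config <- function(config) {
  template <- default_config()
  merge_level <- function(user, tmpl, path) {
    unknown <- setdiff(names(user), names(tmpl))
    if (length(unknown) > 0) {
      stop("unknown config key(s) ",
           paste(paste0(path, unknown), collapse = ", "), call. = FALSE)
    }
    for (k in names(user)) {
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]]))) {
        tmpl[[k]] <- merge_level(as.list(user[[k]]), tmpl[[k]],
                                 paste0(path, k, "."))
      } else {
        tmpl[k] <- list(user[[k]])
      }
    }
    tmpl
  }
  out <- merge_level(unclass(config), unclass(template), "")
  with(out$scene, {
    if (coverage_fraction <= 0 || coverage_fraction >= 1) {
      stop("scene.coverage_fraction must be in (0, 1)", call. = FALSE)
    }
  })
  if (out$split$train_fraction <= 0 || out$split$train_fraction >= 1) {
    stop("split.train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (!all(out$features$use %in% FEATURE_ORDER)) {
    stop("features.use must be a subset of ",
         paste(FEATURE_ORDER, collapse = ", "), call. = FALSE)
  }
  class(out) <- "mlpard_config"
  out
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file; parsed, schema-validated and merged
#'   onto [default_config()].
#' @return An `"mlpard_config"`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

config_scene_params <- function(config) {
  sc <- config$scene
  scene_params(green_mean = sc$green_mean, red_mean = sc$red_mean,
               nir_mean = sc$nir_mean,
               noise_sd = sc$noise_sd, noise_scale = sc$noise_scale,
               texture_contrast = sc$texture_contrast,
               patch_scale = sc$patch_scale,
               coverage_fraction = sc$coverage_fraction,
               seed = config$seed)
}

config_train <- function(config, seed) {
  tr <- config$train
  train_config(hidden_count = tr$hidden_count,
               inner_iterations = tr$inner_iterations,
               outer_cycles = tr$outer_cycles, alpha_init = tr$alpha_init,
               alpha_max = tr$alpha_max, alpha_tol = tr$alpha_tol,
               seed = seed)
}

# ---- whole-scene classification ----------------------------------------------

#' Classify every valid pixel of a scene
#'
#' Flattens the feature stack to one row per pixel, applies the frozen
#' training standardization, thresholds the network output, and returns a
#' class raster with codes 1 (target) / 2 (other); masked pixels are NA
#' (no-data) and excluded from the classified count.
#'
#' @param model A trained `"mlp_ard"`.
#' @param stack A `"feature_stack"` with the model's features.
#' @param standardization The training `"standardization_params"`, or NULL
#'   if the model was trained on raw features.
#' @param threshold Decision threshold (ties to class 1).
#' @return A `"classification_map"`: list with `labels` (integer matrix),
#'   `colors` (green = target, yellow = other), `legend`, `n_classified`.
#' @export
classify_scene <- function(model, stack, standardization = NULL,
                           threshold = 0.5) {
  stopifnot(inherits(model, "mlp_ard"), inherits(stack, "feature_stack"))
  if (stack$n != model$n) {
    stop("stack has ", stack$n, " features; model expects ", model$n,
         call. = FALSE)
  }
  X <- vapply(stack$layers, as.numeric,
              numeric(stack$height * stack$width))
  X <- matrix(X, ncol = stack$n, dimnames = list(NULL, stack$features))
  if (!is.null(standardization)) {
    X <- apply_standardization(standardization, X)
  }
  valid <- as.logical(stack$mask)
  labels <- rep(NA_integer_, length(valid))
  if (any(valid)) {
    pred <- predict_labels(model, X[valid, , drop = FALSE], threshold)
    labels[valid] <- ifelse(pred == 1L, 1L, 2L)
  }
  structure(list(labels = matrix(labels, stack$height, stack$width),
                 colors = c(target = "green", other = "yellow"),
                 legend = c("1" = "target weed", "2" = "other vegetation",
                            "NA" = "no data"),
                 n_classified = sum(valid)),
            class = "classification_map")
}

#' @export
print.classification_map <- function(x, ...) {
  cat(sprintf("classification_map: %d x %d (%d pixels classified)\n",
              nrow(x$labels), ncol(x$labels), x$n_classified))
  cat(sprintf("  target weed (green): %d px; other vegetation (yellow): %d px\n",
              sum(x$labels == 1L, na.rm = TRUE),
              sum(x$labels == 2L, na.rm = TRUE)))
  invisible(x)
}

#' Write a classification map
#'
#' Text format: single integer grid with 0 as the no-data code. With
#' `format = "tiff"` a single-band TIFF is written (requires `tiff`); with
#' `format = "png"` a colour quicklook (green = target, yellow = other,
#' grey = no data; requires `png`).
#'
#' @param map A `"classification_map"`.
#' @param path Output path.
#' @param format One of `"text"`, `"tiff"`, `"png"`.
#' @export
write_classification_map <- function(map, path,
                                     format = c("text", "tiff", "png")) {
  format <- match.arg(format)
  labels <- map$labels
  labels[is.na(labels)] <- 0L
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("mlpard-map 1",
                 paste("dims", nrow(labels), ncol(labels)),
                 "codes 0=nodata 1=target(green) 2=other(yellow)"), con)
    writeLines(apply(labels, 1, paste, collapse = " "), con)
  } else if (format == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required for TIFF export", call. = FALSE)
    }
    tiff::writeTIFF(labels / 255, path, bits.per.sample = 8L)
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("the 'png' package is required for PNG export", call. = FALSE)
    }
    rgb <- array(0.5, c(nrow(labels), ncol(labels), 3L))
    tgt <- labels == 1L
    oth <- labels == 2L
    rgb[, , 1][tgt] <- 0;   rgb[, , 2][tgt] <- 0.7; rgb[, , 3][tgt] <- 0
    rgb[, , 1][oth] <- 1;   rgb[, , 2][oth] <- 0.9; rgb[, , 3][oth] <- 0.1
    png::writePNG(rgb, path)
  }
  invisible(path)
}

#' Read a classification map written by [write_classification_map()]
#' (text format).
#'
#' @param path File path.
#' @return Integer label matrix with NA as no-data.
#' @export
read_classification_map <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "mlpard-map 1") {
    stop("not an mlpard map file: ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(lines[2], " ")[[1]][2:3])
  labels <- parse_grid_lines(lines[3 + seq_len(dims[1])], dims[1], dims[2])
  labels <- matrix(as.integer(labels), dims[1], dims[2])
  labels[labels == 0L] <- NA_integer_
  labels
}

# ---- end-to-end pipeline ----------------------------------------------------

pipeline_stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[mlpard] stage %-9s %6.2f s", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full pipeline: simulate, features, fit, evaluate, map
#'
#' Executes every stage under the config's master seed and, when
#' `config$output$dir` is set, writes the artifact bundle: model file,
#' confusion CSV + text report, relevance report CSV, Hinton table CSV,
#' classification map (text, optionally TIFF/PNG), polygon CSV/GeoJSON and
#' a machine-readable `manifest.json` (seed, config hash, metric values —
#' no timestamps, so reruns are byte-comparable).
#'
#' @param config An `"mlpard_config"` (see [default_config()],
#'   [read_config()]).
#' @return Invisibly, a list with the fitted model, evaluation objects,
#'   the classification map, the ground-truth agreement, and the manifest.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- validate_config(config)
  seed <- config$seed

  sim <- pipeline_stage("simulate", {
    cm <- generate_class_map(config$scene$height, config$scene$width,
                             patch_scale = config$scene$patch_scale,
                             coverage_fraction = config$scene$coverage_fraction,
                             seed = seed,
                             pixel_size = config$scene$pixel_size)
    sc <- generate_scene(cm, config_scene_params(config))
    polys <- generate_polygons(cm,
                               n_per_class = c(config$sampling$n_target,
                                               config$sampling$n_other),
                               rect_size = c(config$sampling$rect_height,
                                             config$sampling$rect_width),
                               seed = seed)
    list(class_map = cm, scene = sc, polygons = polys)
  })

  feats <- pipeline_stage("features", {
    stack <- build_feature_stack(sim$scene,
                                 window_size = config$features$window_size,
                                 features = config$features$use)
    dataset <- sample_pixels(stack, sim$polygons)
    balanced <- balance_calibration(dataset, seed = seed)
    split <- split_train_validation(balanced,
                                    train_fraction = config$split$train_fraction,
                                    seed = seed)
    std <- if (isTRUE(config$features$standardize)) {
      fit_standardization(split$train)
    }
    train <- if (is.null(std)) split$train else {
      apply_standardization(std, split$train)
    }
    valid <- if (is.null(std)) split$validation else {
      apply_standardization(std, split$validation)
    }
    list(stack = stack, dataset = dataset, balanced = balanced,
         train = train, validation = valid, standardization = std)
  })

  fit <- pipeline_stage("train", {
    mlp_ard_fit(feats$train, config_train(config, seed))
  })

  eval_res <- pipeline_stage("evaluate", {
    pred <- predict_labels(fit$model, feats$validation$features)
    conf <- confusion_matrix(feats$validation$labels, pred)
    list(confusion = conf, accuracy = overall_accuracy(conf),
         relevance = relevance_report(fit$model, fit$alphas),
         hinton = hinton_export(fit$model))
  })

  map_res <- pipeline_stage("map", {
    cmap <- classify_scene(fit$model, feats$stack, feats$standardization)
    agree <- mean(cmap$labels == sim$class_map$labels, na.rm = TRUE)
    list(map = cmap, agreement_percent = 100 * agree)
  })

  # hash the analysis parameters only (not output paths/formats), so the
  # same scientific run is identifiable wherever its artifacts land
  analysis_cfg <- unclass(config)
  analysis_cfg$output <- NULL
  config_json <- jsonlite::toJSON(analysis_cfg, auto_unbox = TRUE,
                                  digits = NA)
  manifest <- list(
    seed = seed,
    config_hash = fnv1a_hash(as.character(config_json)),
    n_features = feats$stack$n,
    n_groups = length(fit$groups),
    calibration_pixels = feats$balanced$n_pixels,
    training_pixels = feats$train$n_pixels,
    validation_pixels = feats$validation$n_pixels,
    validation_accuracy_percent = eval_res$confusion$accuracy_exact,
    scene_agreement_percent = map_res$agreement_percent,
    pixels_classified = map_res$map$n_classified,
    alphas = as.list(fit$alphas),
    evidence_cycles = nrow(fit$trace)
  )

  out_dir <- config$output$dir
  if (!is.null(out_dir)) {
    pipeline_stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- function(f) file.path(out_dir, f)
      save_mlp_ard(fit, p("model.txt"),
                   standardization = feats$standardization)
      write_confusion_csv(eval_res$confusion, p("confusion.csv"))
      writeLines(utils::capture.output(print(eval_res$confusion)),
                 p("confusion.txt"))
      write.csv(as.data.frame(eval_res$relevance), p("relevance.csv"),
                row.names = FALSE)
      write.csv(as.data.frame(unclass(eval_res$hinton)), p("hinton.csv"))
      writeLines(hinton_text(eval_res$hinton), p("hinton.txt"))
      write_classification_map(map_res$map, p("classification_map.txt"))
      if (isTRUE(config$output$write_tiff) &&
          requireNamespace("tiff", quietly = TRUE)) {
        write_classification_map(map_res$map, p("classification_map.tif"),
                                 format = "tiff")
      }
      if (isTRUE(config$output$write_png) &&
          requireNamespace("png", quietly = TRUE)) {
        write_classification_map(map_res$map, p("classification_map.png"),
                                 format = "png")
      }
      write_polygons_csv(sim$polygons, p("polygons.csv"))
      write_polygons_geojson(sim$polygons, p("polygons.geojson"))
      write_class_map(sim$class_map, p("ground_truth.txt"))
      jsonlite::write_json(manifest, p("manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      NULL
    })
  }

  invisible(list(class_map = sim$class_map, scene = sim$scene,
                 polygons = sim$polygons, stack = feats$stack,
                 standardization = feats$standardization,
                 train = feats$train, validation = feats$validation,
                 fit = fit, confusion = eval_res$confusion,
                 relevance = eval_res$relevance, hinton = eval_res$hinton,
                 map = map_res$map,
                 agreement_percent = map_res$agreement_percent,
                 manifest = manifest))
}
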