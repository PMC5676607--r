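# Whole-scene classification, configuration handling and the end-to-end
# pipeline.

# a small but non-degenerate pipeline config for these tests
small_config <- function(seed = 0) {
  cfg <- default_config(seed = seed)
  cfg$scene$height <- 96L
  cfg$scene$width <- 96L
  cfg$scene$patch_scale <- 12
  cfg$sampling$n_target <- 6L
  cfg$sampling$n_other <- 5L
  cfg$sampling$rect_height <- 4L
  cfg$sampling$rect_width <- 4L
  cfg$train$inner_iterations <- 60L
  cfg$train$outer_cycles <- 4L
  validate_config(cfg)
}

test_that("classify_scene equals predict_labels applied pixel by pixel", {
  cm <- small_class_map(seed = 1)
  sc <- generate_scene(cm, small_scene_params(seed = 1))
  st <- build_feature_stack(sc)
  m <- nir_gate_model()
  std <- structure(list(center = c(green = 0.1, red = 0.1, nir = 0.4,
                                   texture = 0.001),
                        scale = c(green = 1, red = 1, nir = 1,
                                  texture = 1)),
                   class = "standardization_params")
  cmap <- classify_scene(m, st, std)
  X <- cbind(green = as.numeric(st$layers$green),
             red = as.numeric(st$layers$red),
             nir = as.numeric(st$layers$nir),
             texture = as.numeric(st$layers$texture))
  ref <- predict_labels(m, apply_standardization(std, X))
  expect_identical(as.integer(cmap$labels),
                   ifelse(ref == 1L, 1L, 2L))
  expect_equal(cmap$n_classified, cm$height * cm$width)
})

test_that("a uniform target-exemplar scene maps to a uniform class-1 map", {
  h <- 10L
  bands <- list(green = matrix(0.13, h, h), red = matrix(0.10, h, h),
                nir = matrix(0.55, h, h))
  sc <- spectral_scene(bands$green, bands$red, bands$nir)
  st <- build_feature_stack(sc)
  std <- structure(list(center = c(green = 0.12, red = 0.11, nir = 0.4,
                                   texture = 0.001),
                        scale = c(green = 1, red = 1, nir = 1,
                                  texture = 1)),
                   class = "standardization_params")
  cmap <- classify_scene(nir_gate_model(), st, std)
  expect_true(all(cmap$labels == 1L))
})

test_that("masked pixels become no-data and are excluded from counts", {
  h <- 8L
  mask <- matrix(TRUE, h, h)
  mask[1:2, ] <- FALSE
  sc <- spectral_scene(matrix(0.1, h, h), matrix(0.1, h, h),
                       matrix(0.5, h, h), mask = mask)
  st <- build_feature_stack(sc)
  std <- fit_standardization(pixel_dataset(
    matrix(rnorm(40), 10, 4,
           dimnames = list(NULL, c("green", "red", "nir", "texture"))),
    rep(c(0L, 1L), 5)))
  cmap <- classify_scene(nir_gate_model(), st, std)
  expect_true(all(is.na(cmap$labels[1:2, ])))
  expect_false(anyNA(cmap$labels[3:8, ]))
  expect_equal(cmap$n_classified, sum(mask))
})

test_that("feature-count mismatches are rejected", {
  cm <- small_class_map(seed = 2)
  sc <- generate_scene(cm, small_scene_params(seed = 2))
  st3 <- build_feature_stack(sc, features = c("green", "red", "nir"))
  expect_error(classify_scene(nir_gate_model(), st3), "features")
})

test_that("config validation rejects unknown keys and bad ranges", {
  cfg <- default_config()
  cfg$scene$bogus_key <- 1
  expect_error(validate_config(cfg), "bogus_key")
  cfg2 <- default_config()
  cfg2$split$train_fraction <- 1.5
  expect_error(validate_config(cfg2), "train_fraction")
  # YAML round trip
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 3, scene = list(height = 120, width = 120,
                                               patch_scale = 15)), path)
  cfg3 <- read_config(path)
  expect_equal(cfg3$scene$height, 120)
  expect_equal(cfg3$seed, 3)
  expect_equal(cfg3$split$train_fraction, 0.7) # default filled in
})

test_that("pipeline completes with three features and 3+3 weight groups", {
  cfg <- small_config(seed = 1)
  cfg$features$use <- c("green", "red", "nir")
  res <- suppressMessages(run_pipeline(cfg))
  expect_equal(res$stack$n, 3L)
  expect_length(res$fit$groups, 6L)
  expect_equal(res$manifest$n_groups, 6L)
})

test_that("pipeline artifacts are written and internally consistent", {
  out <- withr::local_tempdir()
  cfg <- small_config(seed = 2)
  cfg$output$dir <- out
  res <- suppressMessages(run_pipeline(cfg))
  files <- c("model.txt", "confusion.csv", "confusion.txt",
             "relevance.csv", "hinton.csv", "hinton.txt",
             "classification_map.txt", "polygons.csv",
             "polygons.geojson", "ground_truth.txt", "manifest.json")
  for (f in files) expect_true(file.exists(file.path(out, f)))
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  # manifest accuracy equals a recomputation from the written confusion CSV
  counts <- mlpard:::read_confusion_csv(file.path(out, "confusion.csv"))
  expect_equal(manifest$validation_accuracy_percent,
               100 * sum(diag(counts)) / sum(counts), tolerance = 1e-12)
  # saved model reproduces the in-memory predictions
  loaded <- load_mlp_ard(file.path(out, "model.txt"))
  expect_identical(
    predict_labels(loaded$model, res$validation$features),
    predict_labels(res$fit$model, res$validation$features))
  # written map equals the in-memory map
  expect_identical(read_classification_map(
    file.path(out, "classification_map.txt")), res$map$labels)
})

test_that("reruns with one master seed are byte-identical", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- small_config(seed = 5)
  cfg$output$dir <- out1
  suppressMessages(run_pipeline(cfg))
  cfg$output$dir <- out2
  suppressMessages(run_pipeline(cfg))
  for (f in c("model.txt", "confusion.csv", "relevance.csv",
              "classification_map.txt", "manifest.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     label = f)
  }
})
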