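# Texture layer, feature stacking, polygon sampling, balancing, splitting
# and standardization.

test_that("local variance is zero on constants and matches hand arithmetic", {
  expect_true(all(local_variance(matrix(3.7, 12, 9), 7) == 0))
  b <- matrix(0, 7, 7)
  b[4, 4] <- 1
  lv <- local_variance(b, 7)
  expect_equal(lv[4, 4], 48 / 2401, tolerance = 1e-14)
  expect_error(local_variance(matrix(0, 8, 8), 6), "odd")
  expect_error(local_variance(matrix(c(1, NA, 1, 1), 2, 2), 3), "finite")
})

test_that("local variance matches the loop-based oracle on random grids", {
  for (s in 1:3) {
    set.seed(s)
    b <- matrix(runif(400), 20, 20)
    expect_equal(local_variance(b, 7), oracle_local_variance(b, 7),
                 tolerance = 1e-12)
    expect_equal(local_variance(b, 3), oracle_local_variance(b, 3),
                 tolerance = 1e-12)
  }
})

test_that("feature stack has the fixed layer order and a texture layer", {
  cm <- small_class_map(seed = 1)
  sc <- generate_scene(cm, small_scene_params(seed = 1))
  st <- build_feature_stack(sc)
  expect_identical(st$features, c("green", "red", "nir", "texture"))
  expect_equal(st$n, 4L)
  expect_equal(st$layers$texture, local_variance(st$layers$nir, 7))
  # constant NIR -> all-zero texture
  flat <- spectral_scene(sc$bands$green, sc$bands$red,
                         matrix(0.4, cm$height, cm$width))
  expect_true(all(build_feature_stack(flat)$layers$texture == 0))
  # feature subsets keep storage order
  st3 <- build_feature_stack(sc, features = c("nir", "green", "red"))
  expect_identical(st3$features, c("green", "red", "nir"))
  expect_equal(st3$n, 3L)
})

test_that("sample_pixels returns one labelled row per covered cell", {
  cm <- small_class_map(seed = 2)
  sc <- generate_scene(cm, small_scene_params(seed = 2))
  st <- build_feature_stack(sc)
  rect <- data.frame(class = 1L, row = 10L, col = 20L, height = 3L,
                     width = 4L)
  ds <- sample_pixels(st, rect)
  expect_equal(ds$n_pixels, 12L)
  expect_true(all(ds$labels == 1L))
  # features equal the stack values at the provenance coordinates
  for (i in seq_len(ds$n_pixels)) {
    for (f in st$features) {
      expect_identical(unname(ds$features[i, f]),
                       st$layers[[f]][ds$coords$row[i], ds$coords$col[i]])
    }
  }
  # overlap is deduplicated; out-of-bounds rejected
  two <- rbind(rect, data.frame(class = 1L, row = 11L, col = 21L,
                                height = 3L, width = 4L))
  expect_lt(sample_pixels(st, two)$n_pixels, 24L)
  expect_error(sample_pixels(st, data.frame(class = 2L, row = 79L,
                                            col = 1L, height = 5L,
                                            width = 2L)),
               "outside")
})

test_that("polygon sampling labels match the ground truth everywhere", {
  cm <- small_class_map(seed = 3)
  sc <- generate_scene(cm, small_scene_params(seed = 3))
  st <- build_feature_stack(sc)
  polys <- generate_polygons(cm, n_per_class = c(6, 5), rect_size = 4,
                             seed = 3)
  ds <- sample_pixels(st, polys)
  expect_equal(ds$n_pixels, 11L * 16L)
  truth <- cm$labels[cbind(ds$coords$row, ds$coords$col)]
  expect_identical(ds$labels, ifelse(truth == 1L, 1L, 0L))
})

test_that("balancing undersamples the majority class reproducibly", {
  ds <- blob_dataset(n_per_class = 10, seed = 1)
  ds_skew <- mlpard:::subset_pixels(ds, c(1:10, 11:13)) # 10 target, 3 other
  bal <- balance_calibration(ds_skew, seed = 5)
  expect_equal(bal$n_pixels, 6L)
  expect_equal(sum(bal$labels == 1L), 3L)
  expect_identical(balance_calibration(ds_skew, seed = 5)$features,
                   bal$features)
  # already balanced: membership unchanged as a set
  bal2 <- balance_calibration(ds, seed = 2)
  expect_equal(bal2$n_pixels, 20L)
  expect_setequal(asplit(bal2$features, 1), asplit(ds$features, 1))
  # single class errors
  only1 <- mlpard:::subset_pixels(ds, 1:10)
  expect_error(balance_calibration(only1, seed = 1), "both classes")
})

test_that("the 70/30 split partitions the data with ceil rounding", {
  ds <- blob_dataset(n_per_class = 5, seed = 2) # N = 10
  sp <- split_train_validation(ds, 0.7, seed = 1)
  expect_equal(sp$train$n_pixels, 7L)
  expect_equal(sp$validation$n_pixels, 3L)
  # disjoint and exhaustive by provenance-free row identity
  all_rows <- rbind(sp$train$features, sp$validation$features)
  expect_setequal(asplit(all_rows, 1), asplit(ds$features, 1))
  sp2 <- split_train_validation(ds, 0.7, seed = 1)
  expect_identical(sp$train$features, sp2$train$features)
  expect_error(split_train_validation(ds, 0.999, seed = 1), "empty")
})

test_that("standardization centers training data and stays frozen", {
  ds <- blob_dataset(n_per_class = 30, seed = 3)
  sp <- split_train_validation(ds, 0.7, seed = 3)
  std <- fit_standardization(sp$train)
  tr <- apply_standardization(std, sp$train)
  expect_true(all(abs(colMeans(tr$features)) < 1e-12))
  expect_equal(unname(apply(tr$features, 2, sd)), rep(1, 4),
               tolerance = 1e-12)
  # frozen params applied to validation differ from re-fitting there
  va <- apply_standardization(std, sp$validation)
  refit <- apply_standardization(fit_standardization(sp$validation),
                                 sp$validation)
  expect_false(isTRUE(all.equal(va$features, refit$features)))
  # constant feature floored with a warning
  feats <- cbind(ds$features[, 1:3], const = 1)
  dc <- pixel_dataset(feats, ds$labels)
  expect_warning(stdc <- fit_standardization(dc), "floored")
  expect_true(all(is.finite(apply_standardization(stdc, dc)$features)))
})

test_that("block-mean resampling averages factor x factor blocks", {
  m <- matrix(1:16, 4, 4)
  r <- block_mean_resample(m, 2)
  expect_equal(r[1, 1], mean(m[1:2, 1:2]))
  expect_equal(r[2, 2], mean(m[3:4, 3:4]))
  expect_equal(dim(block_mean_resample(matrix(0, 7, 9), 2)), c(3L, 4L))
})

test_that("scene -> stack -> sample -> balance -> split is bit-reproducible", {
  run_once <- function() {
    cm <- small_class_map(seed = 9)
    sc <- generate_scene(cm, small_scene_params(seed = 9))
    st <- build_feature_stack(sc)
    polys <- generate_polygons(cm, n_per_class = c(5, 4), rect_size = 4,
                               seed = 9)
    ds <- balance_calibration(sample_pixels(st, polys), seed = 9)
    split_train_validation(ds, 0.7, seed = 9)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$train$features, b$train$features)
  expect_identical(a$validation$labels, b$validation$labels)
  expect_identical(a$train$coords, b$train$coords)
})
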