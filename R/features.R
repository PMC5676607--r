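# Texture layer, feature stacking, polygon sampling, class balancing,
# 70/30 calibration/validation split, and input standardization.

# ---- texture ----------------------------------------------------------------

# Centered moving-window mean over each cell of a reflect-padded matrix.
box_mean <- function(mat, window_size) {
  r <- (window_size - 1L) %/% 2L
  k <- rep(1 / window_size, window_size)
  pad <- reflect_pad(mat, r)
  pass1 <- filter_cols(pad, k)
  pass2 <- t(filter_cols(t(pass1), k))
  pass2[seq_len(nrow(mat)) + r, seq_len(ncol(mat)) + r, drop = FALSE]
}

#' Local-variance texture layer
#'
#' Per-pixel population variance (divide-by-count) of the
#' `window_size x window_size` neighbourhood centred on the pixel, the
#' standard texture measure for vegetation canopy roughness. Edge
#' neighbourhoods are completed by reflect padding (mirror without
#' duplicating the edge sample), so the output has the shape of the input.
#'
#' @param band Finite numeric matrix (typically the NIR band).
#' @param window_size Odd integer >= 3; default 7.
#' @return Matrix of the same shape, non-negative everywhere.
#' @export
#' @examples
#' b <- matrix(0, 7, 7); b[4, 4] <- 1
#' local_variance(b)[4, 4] # 48/2401
local_variance <- function(band, window_size = 7L) {
  if (length(window_size) != 1L || window_size < 3L ||
      window_size %% 2L == 0L) {
    stop("window_size must be an odd integer >= 3", call. = FALSE)
  }
  stopifnot(is.matrix(band))
  if (!all(is.finite(band))) {
    stop("band must be finite everywhere", call. = FALSE)
  }
  # centre on the grand mean first to avoid cancellation in E[x^2] - E[x]^2
  centred <- band - mean(band)
  m1 <- box_mean(centred, window_size)
  m2 <- box_mean(centred * centred, window_size)
  pmax(m2 - m1 * m1, 0)
}

# ---- feature stack ----------------------------------------------------------

#' Stack input features for classification
#'
#' Builds the model's input layers in fixed storage order green, red, nir,
#' texture, where texture is the local variance of the NIR band
#' ([local_variance()], 7x7 by default). A subset of features can be
#' selected (e.g. dropping texture for a 3-feature model); order within the
#' subset follows the storage order.
#'
#' @param scene A `"spectral_scene"`.
#' @param window_size Local-variance window (odd, >= 3).
#' @param features Character subset of
#'   `c("green", "red", "nir", "texture")`.
#' @return A `"feature_stack"`: list with `layers` (named list of matrices),
#'   `features`, `n`, `mask`, `height`, `width`.
#' @export
build_feature_stack <- function(scene, window_size = 7L,
                                features = FEATURE_ORDER) {
  stopifnot(inherits(scene, "spectral_scene"))
  features <- match.arg(features, FEATURE_ORDER, several.ok = TRUE)
  features <- FEATURE_ORDER[FEATURE_ORDER %in% features]
  layers <- list()
  for (f in features) {
    layers[[f]] <- if (f == "texture") {
      local_variance(scene$bands$nir, window_size)
    } else {
      scene$bands[[f]]
    }
  }
  structure(list(layers = layers, features = features,
                 n = length(features), mask = scene$mask,
                 height = scene$height, width = scene$width,
                 window_size = window_size),
            class = "feature_stack")
}

# ---- pixel dataset ----------------------------------------------------------

#' Construct a labelled pixel dataset
#'
#' @param features Numeric matrix, one row per pixel, named feature columns.
#' @param labels Integer vector in `{0, 1}` (1 = target class), one per row.
#' @param coords Data frame with columns `row`, `col` giving each pixel's
#'   source coordinates (1-based); optional.
#' @return A `"pixel_dataset"` list with `features`, `labels`, `coords`,
#'   `n_pixels`.
#' @export
pixel_dataset <- function(features, labels, coords = NULL) {
  stopifnot(is.matrix(features), is.numeric(features))
  labels <- as.integer(labels)
  if (length(labels) != nrow(features) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1, one per feature row", call. = FALSE)
  }
  if (is.null(coords)) {
    coords <- data.frame(row = rep(NA_integer_, nrow(features)),
                         col = rep(NA_integer_, nrow(features)))
  }
  stopifnot(nrow(coords) == nrow(features),
            all(c("row", "col") %in% names(coords)))
  structure(list(features = features, labels = labels,
                 coords = coords[c("row", "col")],
                 n_pixels = nrow(features)),
            class = "pixel_dataset")
}

#' @export
print.pixel_dataset <- function(x, ...) {
  cat(sprintf("pixel_dataset: %d pixels x %d features (%s)\n",
              x$n_pixels, ncol(x$features),
              paste(colnames(x$features), collapse = ", ")))
  cat(sprintf("  class counts: target %d, other %d\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

subset_pixels <- function(dataset, idx) {
  pixel_dataset(dataset$features[idx, , drop = FALSE],
                dataset$labels[idx],
                dataset$coords[idx, , drop = FALSE])
}

#' Sample labelled pixels from polygons
#'
#' One row per polygon-covered cell; feature values are read off the stack
#' at the cell's coordinates and the label comes from the polygon's class
#' (target -> 1, other -> 0). Cells covered by more than one polygon are
#' kept once (first polygon wins).
#'
#' @param stack A `"feature_stack"`.
#' @param polygons A `"polygon_set"` (or data.frame with columns `class`,
#'   `row`, `col`, `height`, `width`).
#' @return A `"pixel_dataset"` with provenance coordinates.
#' @export
sample_pixels <- function(stack, polygons) {
  stopifnot(inherits(stack, "feature_stack"),
            all(c("class", "row", "col", "height", "width") %in%
                  names(polygons)))
  rows <- integer(0)
  cols <- integer(0)
  labs <- integer(0)
  for (p in seq_len(nrow(polygons))) {
    r0 <- polygons$row[p]
    c0 <- polygons$col[p]
    r1 <- r0 + polygons$height[p] - 1L
    c1 <- c0 + polygons$width[p] - 1L
    if (r0 < 1L || c0 < 1L || r1 > stack$height || c1 > stack$width) {
      stop("polygon ", p, " extends outside the ", stack$height, "x",
           stack$width, " grid", call. = FALSE)
    }
    cells <- expand.grid(row = r0:r1, col = c0:c1)
    rows <- c(rows, cells$row)
    cols <- c(cols, cells$col)
    labs <- c(labs, rep(if (polygons$class[p] == 1L) 1L else 0L,
                        nrow(cells)))
  }
  keep <- !duplicated(cbind(rows, cols))
  rows <- rows[keep]
  cols <- cols[keep]
  labs <- labs[keep]
  idx <- cbind(rows, cols)
  feats <- vapply(stack$layers, function(l) l[idx], numeric(length(rows)))
  feats <- matrix(feats, nrow = length(rows),
                  dimnames = list(NULL, stack$features))
  pixel_dataset(feats, labs, data.frame(row = rows, col = cols))
}

# ---- balancing and splitting ------------------------------------------------

#' Balance a calibration set by undersampling the majority class
#'
#' The majority class is randomly undersampled without replacement (seeded)
#' to the minority count, then the combined set is deterministically
#' shuffled, yielding `2 * min(class counts)` pixels with equal class
#' representation.
#'
#' @param dataset A `"pixel_dataset"` containing both classes.
#' @param seed Integer master seed (child stream label `"balance"`).
#' @return A balanced `"pixel_dataset"` (a subset of the input).
#' @export
balance_calibration <- function(dataset, seed = 0L) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  idx1 <- which(dataset$labels == 1L)
  idx0 <- which(dataset$labels == 0L)
  if (length(idx1) == 0L || length(idx0) == 0L) {
    stop("both classes must be present to balance the calibration set",
         call. = FALSE)
  }
  m <- min(length(idx1), length(idx0))
  keep <- with_seed(derive_seed(seed, "balance"), {
    k1 <- if (length(idx1) > m) sort(sample(idx1, m)) else idx1
    k0 <- if (length(idx0) > m) sort(sample(idx0, m)) else idx0
    all_idx <- c(k1, k0)
    all_idx[sample.int(length(all_idx))]
  })
  subset_pixels(dataset, keep)
}

#' Split a dataset into training and validation subsets
#'
#' Seeded random assignment: the training side gets
#' `ceiling(train_fraction * N)` pixels (so a 70% split of 2868 pixels
#' yields 2008 training and 860 validation pixels), the validation side the
#' complement; the two are disjoint and exhaustive.
#'
#' @param dataset A `"pixel_dataset"` with at least 2 pixels.
#' @param train_fraction In (0, 1); default 0.7.
#' @param seed Integer master seed (child stream label `"split"`).
#' @return List with elements `train` and `validation`.
#' @export
split_train_validation <- function(dataset, train_fraction = 0.7,
                                   seed = 0L) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  n <- dataset$n_pixels
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- as.integer(ceiling(train_fraction * n))
  if (n_train == 0L || n_train == n) {
    stop("split leaves one side empty (N = ", n, ", fraction = ",
         train_fraction, ")", call. = FALSE)
  }
  tr <- with_seed(derive_seed(seed, "split"), sort(sample.int(n, n_train)))
  list(train = subset_pixels(dataset, tr),
       validation = subset_pixels(dataset, setdiff(seq_len(n), tr)))
}

# ---- standardization --------------------------------------------------------

#' Fit per-feature standardization on training data
#'
#' Location = column mean, scale = column standard deviation, estimated on
#' the training set only and frozen for validation and whole-scene use.
#' A zero-variance feature has its scale floored at `1e-8` with a warning.
#'
#' @param train A non-empty `"pixel_dataset"`.
#' @return A `"standardization_params"` list with named `center` and
#'   `scale` vectors.
#' @export
fit_standardization <- function(train) {
  stopifnot(inherits(train, "pixel_dataset"), train$n_pixels > 0L)
  center <- colMeans(train$features)
  scale <- apply(train$features, 2, stats::sd)
  floored <- scale < 1e-8 | !is.finite(scale)
  if (any(floored)) {
    warning("feature(s) ", paste(names(scale)[floored], collapse = ", "),
            " have (near-)zero variance; scale floored at 1e-8",
            call. = FALSE)
    scale[floored] <- 1e-8
  }
  structure(list(center = center, scale = scale),
            class = "standardization_params")
}

#' Apply frozen standardization parameters
#'
#' @param params A `"standardization_params"` from [fit_standardization()].
#' @param x A `"pixel_dataset"`, a `"feature_stack"`, or a numeric matrix
#'   with columns in the same feature order.
#' @return An object of the same type with features mapped to
#'   (x - center) / scale.
#' @export
apply_standardization <- function(params, x) {
  stopifnot(inherits(params, "standardization_params"))
  std_matrix <- function(m) {
    sweep(sweep(m, 2, params$center, "-"), 2, params$scale, "/")
  }
  if (inherits(x, "pixel_dataset")) {
    out <- x
    out$features <- std_matrix(x$features)
    out
  } else if (inherits(x, "feature_stack")) {
    stopifnot(identical(x$features, names(params$center)))
    out <- x
    for (f in x$features) {
      out$layers[[f]] <- (x$layers[[f]] - params$center[[f]]) /
        params$scale[[f]]
    }
    out
  } else if (is.matrix(x)) {
    std_matrix(x)
  } else {
    stop("cannot standardize object of class ", class(x)[1], call. = FALSE)
  }
}

# ---- resampling plumbing ----------------------------------------------------

#' Block-mean resampling of a grid
#'
#' Aggregates `factor x factor` pixel blocks by their mean, e.g. to bring a
#' 0.1 m grid to 0.5 m analysis resolution with `factor = 5`. Trailing rows
#' and columns that do not fill a block are dropped.
#'
#' @param mat Numeric matrix.
#' @param factor Positive integer block edge.
#' @return Matrix of size `floor(dim / factor)`.
#' @export
block_mean_resample <- function(mat, factor) {
  stopifnot(is.matrix(mat), factor >= 1, factor == as.integer(factor))
  factor <- as.integer(factor)
  h <- (nrow(mat) %/% factor) * factor
  w <- (ncol(mat) %/% factor) * factor
  if (h == 0L || w == 0L) stop("matrix smaller than one block", call. = FALSE)
  m <- mat[seq_len(h), seq_len(w), drop = FALSE]
  # average rows within blocks, then columns
  rowagg <- rowsum(m, rep(seq_len(h %/% factor), each = factor)) / factor
  t(rowsum(t(rowagg), rep(seq_len(w %/% factor), each = factor)) / factor)
}
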