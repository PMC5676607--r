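# Synthetic multispectral scenes with patchy two-class ground truth.
#
# The generator emulates the statistical structure of a field where a tall,
# vigorous broadleaf weed (class 1, e.g. milk thistle) grows in large
# contiguous patches against a background of drying graminaceous vegetation
# (class 2): the target class is brighter and rougher in the NIR band, while
# the green and red bands are nearly uninformative (class means closer than
# one within-class noise standard deviation).

# ---- smoothing primitives ---------------------------------------------------

# Mirror indices for reflect padding (edge sample not duplicated);
# requires r <= n - 1.
reflect_indices <- function(n, r) {
  if (r > n - 1) {
    stop("padding radius ", r, " too large for dimension ", n, call. = FALSE)
  }
  if (r == 0) return(seq_len(n))
  c(rev(seq_len(r) + 1L), seq_len(n), n - seq_len(r))
}

reflect_pad <- function(mat, r) {
  mat[reflect_indices(nrow(mat), r), reflect_indices(ncol(mat), r),
      drop = FALSE]
}

# Centered moving-window 1-D convolution of each column of a matrix;
# rows within `radius` of either edge come back NA and must be cropped.
filter_cols <- function(mat, kernel) {
  out <- stats::filter(mat, kernel, method = "convolution", sides = 2)
  matrix(as.numeric(out), nrow(mat), ncol(mat))
}

# Separable convolution with reflect padding; kernel is odd-length 1-D.
separable_smooth <- function(mat, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  pad <- reflect_pad(mat, r)
  pass1 <- filter_cols(pad, kernel)
  pass2 <- t(filter_cols(t(pass1), kernel))
  pass2[seq_len(nrow(mat)) + r, seq_len(ncol(mat)) + r, drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k / sum(k)
}

# White noise convolved with an isotropic Gaussian of sd = scale / 2;
# `scale` is the nominal patch length in pixels. Draws from the caller's
# RNG state.
smooth_random_field <- function(height, width, scale) {
  noise <- matrix(rnorm(height * width), height, width)
  separable_smooth(noise, gaussian_kernel(scale / 2))
}

# ---- domain types -----------------------------------------------------------

#' Parameters of the synthetic scene generator
#'
#' Defaults encode the qualitative contrast the analysis relies on: the
#' target class is much brighter in the NIR (vigorous canopy vs. drying
#' grass), carries extra high-frequency NIR noise (structural texture of
#' large discrete plants), and is nearly indistinguishable in green and red
#' (class mean difference below one within-class noise sd). Reflectances
#' are on a 0-1 scale.
#'
#' @param green_mean,red_mean,nir_mean Length-2 numeric `c(target, other)`
#'   class mean reflectances per band.
#' @param noise_sd Named numeric, within-class smooth-noise sd per band.
#' @param noise_scale Smoothing length (pixels) of the within-class noise
#'   fields.
#' @param texture_contrast Sd of the independent high-frequency noise added
#'   to the target class's NIR band; this is what makes the 7x7 local
#'   variance separate the classes. `0` disables it.
#' @param patch_scale Smoothing length (pixels) of the patch field.
#' @param coverage_fraction Areal fraction of the target class, in (0, 1).
#' @param seed Integer master seed for the generator.
#' @return A list of class `"scene_params"`.
#' @export
#' @examples
#' p <- scene_params(coverage_fraction = 0.3)
#' p$nir_mean
scene_params <- function(green_mean = c(target = 0.13, other = 0.12),
                         red_mean = c(target = 0.10, other = 0.11),
                         nir_mean = c(target = 0.55, other = 0.30),
                         noise_sd = c(green = 0.02, red = 0.02, nir = 0.03),
                         noise_scale = 5,
                         texture_contrast = 0.08,
                         patch_scale = 40,
                         coverage_fraction = 0.4,
                         seed = 0L) {
  for (m in list(green_mean, red_mean, nir_mean)) {
    stopifnot(length(m) == 2L, all(is.finite(m)), all(m >= 0))
  }
  stopifnot(length(noise_sd) == 3L, all(noise_sd >= 0), noise_scale > 0,
            texture_contrast >= 0, patch_scale >= 1)
  if (coverage_fraction <= 0 || coverage_fraction >= 1) {
    stop("coverage_fraction must be in (0, 1)", call. = FALSE)
  }
  names(noise_sd) <- c("green", "red", "nir")
  structure(list(green_mean = stats::setNames(green_mean, c("target", "other")),
                 red_mean = stats::setNames(red_mean, c("target", "other")),
                 nir_mean = stats::setNames(nir_mean, c("target", "other")),
                 noise_sd = noise_sd, noise_scale = noise_scale,
                 texture_contrast = texture_contrast,
                 patch_scale = patch_scale,
                 coverage_fraction = coverage_fraction,
                 seed = as.integer(seed)),
            class = "scene_params")
}

new_class_map <- function(labels, pixel_size, seed) {
  stopifnot(is.matrix(labels), all(labels %in% c(1L, 2L)))
  structure(list(labels = labels, height = nrow(labels),
                 width = ncol(labels), pixel_size = pixel_size,
                 seed = seed),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("class_map: %d x %d pixels (%.3g ground units/pixel)\n",
              x$height, x$width, x$pixel_size))
  cat(sprintf("  target class (1) fraction: %.3f\n",
              mean(x$labels == 1L)))
  invisible(x)
}

#' Construct a spectral scene from band matrices
#'
#' @param green,red,nir Same-shape numeric matrices of reflectances
#'   (finite, non-negative).
#' @param mask Logical validity matrix (TRUE = valid pixel); defaults to
#'   all valid.
#' @param pixel_size Ground units per pixel (metadata only).
#' @return A list of class `"spectral_scene"` with elements `bands`
#'   (named list green/red/nir), `mask`, `height`, `width`.
#' @export
spectral_scene <- function(green, red, nir, mask = NULL, pixel_size = 0.5) {
  bands <- list(green = green, red = red, nir = nir)
  dims <- dim(green)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (!is.matrix(b) || !identical(dim(b), dims)) {
      stop("band '", nm, "' does not match the shape of the others",
           call. = FALSE)
    }
    if (!all(is.finite(b)) || any(b < 0)) {
      stop("band '", nm, "' must be finite and non-negative", call. = FALSE)
    }
  }
  if (is.null(mask)) mask <- matrix(TRUE, dims[1], dims[2])
  stopifnot(is.logical(mask), identical(dim(mask), dims))
  structure(list(bands = bands, mask = mask, height = dims[1],
                 width = dims[2], pixel_size = pixel_size),
            class = "spectral_scene")
}

#' @export
print.spectral_scene <- function(x, ...) {
  cat(sprintf("spectral_scene: %d x %d pixels, bands green/red/nir\n",
              x$height, x$width))
  for (nm in names(x$bands)) {
    cat(sprintf("  %-6s mean %.4f  sd %.4f\n", nm,
                mean(x$bands[[nm]]), stats::sd(x$bands[[nm]])))
  }
  invisible(x)
}

# ---- generators -------------------------------------------------------------

#' Generate a patchy two-class ground-truth map
#'
#' A Gaussian white-noise field is smoothed with an isotropic kernel of
#' length `patch_scale` and thresholded at its empirical
#' `(1 - coverage_fraction)` quantile, so the target class (code 1) occupies
#' `coverage_fraction` of the cells (within quantile granularity) in large
#' contiguous patches interleaved with the background class (code 2).
#'
#' @param height,width Grid size in pixels; each must be at least
#'   `4 * patch_scale`.
#' @param patch_scale Smoothing length of the patch field, in pixels.
#' @param coverage_fraction Target-class areal fraction, in (0, 1).
#' @param seed Integer master seed (child stream label `"class_map"`).
#' @param pixel_size Ground units per pixel (metadata only).
#' @return A `"class_map"` object.
#' @export
#' @examples
#' cm <- generate_class_map(80, 80, patch_scale = 10,
#'                          coverage_fraction = 0.4, seed = 1)
#' mean(cm$labels == 1)
generate_class_map <- function(height, width, patch_scale = 15,
                               coverage_fraction = 0.4, seed = 0L,
                               pixel_size = 0.5) {
  stopifnot(patch_scale >= 1)
  if (height < 4 * patch_scale || width < 4 * patch_scale) {
    stop("grid too small: height and width must each be at least 4 * ",
         "patch_scale (", 4 * patch_scale, ")", call. = FALSE)
  }
  if (coverage_fraction <= 0 || coverage_fraction >= 1) {
    stop("coverage_fraction must be in (0, 1)", call. = FALSE)
  }
  field <- with_seed(derive_seed(seed, "class_map"),
                     smooth_random_field(height, width, patch_scale))
  thr <- quantile(field, 1 - coverage_fraction, names = FALSE)
  labels <- matrix(2L, height, width)
  labels[field > thr] <- 1L
  new_class_map(labels, pixel_size, as.integer(seed))
}

#' Generate a synthetic multispectral scene over a class map
#'
#' Each band is its class mean plus a smooth within-class noise field
#' (scaled to the band's noise sd); target-class NIR cells additionally
#' receive independent high-frequency noise of sd `texture_contrast`, so
#' the 7x7 local variance of the NIR band is stochastically larger inside
#' target patches. Reflectances are clamped at zero.
#'
#' @param class_map A `"class_map"`.
#' @param params A [scene_params()] object; its `seed` drives the band and
#'   texture noise streams.
#' @return A `"spectral_scene"`.
#' @export
#' @examples
#' cm <- generate_class_map(80, 80, patch_scale = 10, seed = 1)
#' sc <- generate_scene(cm, scene_params(seed = 1))
generate_scene <- function(class_map, params = scene_params()) {
  stopifnot(inherits(class_map, "class_map"),
            inherits(params, "scene_params"))
  h <- class_map$height
  w <- class_map$width
  target <- class_map$labels == 1L
  bands <- list()
  for (band in c("green", "red", "nir")) {
    means <- params[[paste0(band, "_mean")]]
    base <- matrix(means[["other"]], h, w)
    base[target] <- means[["target"]]
    sdv <- params$noise_sd[[band]]
    if (sdv > 0) {
      f <- with_seed(derive_seed(params$seed, paste0("scene/", band)),
                     smooth_random_field(h, w, params$noise_scale))
      base <- base + sdv * f / stats::sd(f)
    }
    bands[[band]] <- base
  }
  if (params$texture_contrast > 0 && any(target)) {
    tex <- with_seed(derive_seed(params$seed, "scene/texture"),
                     matrix(rnorm(h * w), h, w))
    bands$nir[target] <- bands$nir[target] +
      params$texture_contrast * tex[target]
  }
  bands <- lapply(bands, function(b) pmax(b, 0))
  spectral_scene(bands$green, bands$red, bands$nir,
                 pixel_size = class_map$pixel_size)
}

# Top-left positions (i, j) where an rh x rw rectangle lies entirely on
# cells of class `cls`, via an integral image of the class indicator.
pure_topleft_positions <- function(labels, cls, rh, rw) {
  h <- nrow(labels)
  w <- ncol(labels)
  if (rh > h || rw > w) return(matrix(integer(0), 0, 2))
  ind <- matrix(0, h + 1, w + 1)
  ind[-1, -1] <- (labels == cls) + 0
  s <- apply(apply(ind, 2, cumsum), 1, cumsum)
  s <- t(s)
  i <- seq_len(h - rh + 1)
  j <- seq_len(w - rw + 1)
  win <- s[i + rh, j + rw, drop = FALSE] - s[i, j + rw, drop = FALSE] -
    s[i + rh, j, drop = FALSE] + s[i, j, drop = FALSE]
  which(win == rh * rw, arr.ind = TRUE)
}

#' Place pure-class sampling rectangles on a class map
#'
#' Emulates the ground-truth survey polygons of a field campaign: a
#' configurable number of axis-aligned rectangles per class, each lying
#' entirely on cells of its own class and pairwise disjoint. Placement is
#' a seeded random shuffle of all feasible top-left positions with greedy
#' non-overlap acceptance, so output is deterministic for a fixed seed.
#'
#' @param class_map A `"class_map"`.
#' @param n_per_class Length-2 integer `c(target, other)`: rectangle counts
#'   per class (e.g. `c(17, 13)`).
#' @param rect_size Length-2 integer `c(height, width)` of every rectangle,
#'   or a scalar for squares.
#' @param seed Integer master seed (child stream label `"polygons"`).
#' @return A `"polygon_set"`: a data.frame with columns `class`, `row`,
#'   `col`, `height`, `width` (1-based top-left corner, closed extents).
#' @export
#' @examples
#' cm <- generate_class_map(120, 120, patch_scale = 12, seed = 3)
#' polys <- generate_polygons(cm, n_per_class = c(5, 4), rect_size = 4,
#'                            seed = 3)
#' table(polys$class)
generate_polygons <- function(class_map, n_per_class = c(17, 13),
                              rect_size = c(4, 4), seed = 0L) {
  stopifnot(inherits(class_map, "class_map"), length(n_per_class) == 2L,
            all(n_per_class >= 1))
  if (length(rect_size) == 1L) rect_size <- c(rect_size, rect_size)
  rh <- as.integer(rect_size[1])
  rw <- as.integer(rect_size[2])
  stopifnot(rh >= 1, rw >= 1)
  labels <- class_map$labels
  occupied <- matrix(FALSE, nrow(labels), ncol(labels))
  class_names <- c("target", "other")
  out <- list()
  for (ci in 1:2) {
    pos <- pure_topleft_positions(labels, ci, rh, rw)
    if (nrow(pos) > 0) {
      pos <- pos[with_seed(derive_seed(seed, paste0("polygons/", ci)),
                           sample.int(nrow(pos))), , drop = FALSE]
    }
    placed <- 0L
    rows <- integer(0)
    cols <- integer(0)
    for (p in seq_len(nrow(pos))) {
      i <- pos[p, 1]
      j <- pos[p, 2]
      cells_i <- i:(i + rh - 1L)
      cells_j <- j:(j + rw - 1L)
      if (any(occupied[cells_i, cells_j])) next
      occupied[cells_i, cells_j] <- TRUE
      placed <- placed + 1L
      rows <- c(rows, i)
      cols <- c(cols, j)
      if (placed == n_per_class[ci]) break
    }
    if (placed < n_per_class[ci]) {
      stop("could not place ", n_per_class[ci], " disjoint pure ", rh, "x",
           rw, " rectangles for class '", class_names[ci],
           "' (placed ", placed, "); use a larger scene, larger patches ",
           "or smaller rectangles", call. = FALSE)
    }
    out[[ci]] <- data.frame(class = ci, row = rows, col = cols,
                            height = rh, width = rw)
  }
  res <- rbind(out[[1]], out[[2]])
  rownames(res) <- NULL
  class(res) <- c("polygon_set", "data.frame")
  attr(res, "n_per_class") <- stats::setNames(as.integer(n_per_class),
                                              class_names)
  res
}
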