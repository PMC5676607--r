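# Readers and writers for the package's on-disk formats.
#
# The primary interchange format is a portable plain-text grid: a header
# line "mlpard-grid 1 <nrow> <ncol>" followed by one image row per line of
# space-separated values printed with "%.17g" (lossless for IEEE doubles).
# Scenes bundle three band grids and a mask in one file; class maps and
# classification maps are single integer grids. Multiband TIFF export
# (32-bit float, no geo tags) and PNG quicklooks are available when the
# tiff/png packages are installed. Polygon sets are written as GeoJSON
# (pixel coordinates, a "class" property) and as a rectangle-bounds CSV.

fmt_num <- function(x) sprintf("%.17g", x)

write_grid_lines <- function(mat) {
  apply(mat, 1, function(row) paste(fmt_num(row), collapse = " "))
}

parse_grid_lines <- function(lines, nrow, ncol) {
  vals <- as.numeric(unlist(strsplit(lines, " ", fixed = TRUE)))
  if (length(vals) != nrow * ncol) {
    stop("grid body has ", length(vals), " values; expected ", nrow * ncol,
         call. = FALSE)
  }
  matrix(vals, nrow, ncol, byrow = TRUE)
}

#' Write / read a spectral scene as a portable text archive
#'
#' @param scene A `"spectral_scene"`.
#' @param path Output file path.
#' @return `path` (write) or a `"spectral_scene"` (read), invisibly for the
#'   writer.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "spectral_scene"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("mlpard-scene 1",
               paste("dims", scene$height, scene$width),
               paste("pixel_size", fmt_num(scene$pixel_size)),
               paste("bands", paste(names(scene$bands), collapse = " "))),
             con)
  for (nm in names(scene$bands)) {
    writeLines(paste("band", nm), con)
    writeLines(write_grid_lines(scene$bands[[nm]]), con)
  }
  writeLines("mask", con)
  writeLines(apply(scene$mask, 1, function(r) {
    paste(as.integer(r), collapse = " ")
  }), con)
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "mlpard-scene 1") {
    stop("not an mlpard scene file: ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(lines[2], " ")[[1]][2:3])
  pixel_size <- as.numeric(strsplit(lines[3], " ")[[1]][2])
  band_names <- strsplit(lines[4], " ")[[1]][-1]
  cursor <- 5L
  bands <- list()
  for (nm in band_names) {
    stopifnot(lines[cursor] == paste("band", nm))
    bands[[nm]] <- parse_grid_lines(lines[cursor + seq_len(dims[1])],
                                    dims[1], dims[2])
    cursor <- cursor + dims[1] + 1L
  }
  stopifnot(lines[cursor] == "mask")
  mask <- parse_grid_lines(lines[cursor + seq_len(dims[1])],
                           dims[1], dims[2]) == 1
  spectral_scene(bands$green, bands$red, bands$nir, mask = mask,
                 pixel_size = pixel_size)
}

#' Write / read a class map as a single-band text raster
#'
#' @param class_map A `"class_map"`.
#' @param path File path.
#' @export
write_class_map <- function(class_map, path) {
  stopifnot(inherits(class_map, "class_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("mlpard-classmap 1",
               paste("dims", class_map$height, class_map$width),
               paste("pixel_size", fmt_num(class_map$pixel_size))), con)
  writeLines(apply(class_map$labels, 1, function(r) {
    paste(r, collapse = " ")
  }), con)
  invisible(path)
}

#' @rdname write_class_map
#' @export
read_class_map <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "mlpard-classmap 1") {
    stop("not an mlpard class-map file: ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(lines[2], " ")[[1]][2:3])
  pixel_size <- as.numeric(strsplit(lines[3], " ")[[1]][2])
  labels <- parse_grid_lines(lines[3 + seq_len(dims[1])], dims[1], dims[2])
  new_class_map(matrix(as.integer(labels), dims[1], dims[2]), pixel_size,
                NA_integer_)
}

#' Export a scene as a 3-band 32-bit float TIFF (band order green, red,
#' NIR; no geo tags). Requires the `tiff` package.
#'
#' @param scene A `"spectral_scene"`.
#' @param path Output `.tif` path.
#' @export
write_scene_tiff <- function(scene, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  }
  arr <- array(0, c(scene$height, scene$width, 3L))
  for (i in 1:3) arr[, , i] <- scene$bands[[i]]
  tiff::writeTIFF(arr, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Write a polygon set as GeoJSON (pixel coordinates, "class" property)
#'
#' Rectangles are emitted as closed Polygon rings in (col, row) coordinate
#' order with a per-feature `class` property (1 = target, 2 = other).
#'
#' @param polygons A `"polygon_set"`.
#' @param path Output `.geojson` path.
#' @export
write_polygons_geojson <- function(polygons, path) {
  features <- lapply(seq_len(nrow(polygons)), function(i) {
    r0 <- polygons$row[i]
    c0 <- polygons$col[i]
    r1 <- r0 + polygons$height[i]
    c1 <- c0 + polygons$width[i]
    ring <- list(c(c0, r0), c(c1, r0), c(c1, r1), c(c0, r1), c(c0, r0))
    list(type = "Feature",
         properties = list(class = polygons$class[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a polygon set as a rectangle-bounds CSV
#'
#' Columns: `class,row,col,height,width` (1-based top-left corner).
#'
#' @param polygons A `"polygon_set"` (or compatible data.frame).
#' @param path File path.
#' @export
write_polygons_csv <- function(polygons, path) {
  write.csv(as.data.frame(polygons)[c("class", "row", "col", "height",
                                      "width")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polygons_csv
#' @export
read_polygons_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("class", "row", "col", "height", "width") %in% names(df)))
  class(df) <- c("polygon_set", "data.frame")
  df
}

#' Write / read a pixel dataset as CSV
#'
#' Columns: `row,col,<feature columns>,label`.
#'
#' @param dataset A `"pixel_dataset"`.
#' @param path File path.
#' @export
write_pixel_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "pixel_dataset"))
  df <- cbind(dataset$coords, as.data.frame(dataset$features),
              label = dataset$labels)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pixel_dataset
#' @export
read_pixel_dataset <- function(path) {
  df <- read.csv(path)
  feat_cols <- setdiff(names(df), c("row", "col", "label"))
  pixel_dataset(as.matrix(df[feat_cols]), df$label,
                df[c("row", "col")])
}
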