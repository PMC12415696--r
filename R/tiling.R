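# Tessellation of a slide-scale image into non-overlapping 512x512 tiles.
# Coordinates are 0-based slide pixels, origin top-left; a tile at (x, y)
# covers the half-open extent [x, x+size) x [y, y+size). The grid is anchored
# at the top-left of the ROI bounding box, and a grid cell becomes a tile iff
# it lies fully inside the image and at least `min_roi_coverage` of its pixels
# are inside the mask. Output order is row-major (x varies fastest).

#' Tessellate a slide ROI into non-overlapping square tiles
#'
#' @param slide_image `(h, w, 3)` RGB array, 0--255.
#' @param roi_mask 0/1 matrix of the same `(h, w)`.
#' @param tile_size Tile edge length in pixels.
#' @param min_roi_coverage Minimum fraction of a grid cell's pixels that must
#'   be inside the mask (`>=` rule).
#' @param slide_id,patient_id Identity attached to each tile.
#' @param label Class label in `{0, 1}` inherited by every tile, or `NA`.
#' @param resolution Microns per pixel, recorded in the tile metadata.
#' @return A `tile_set`: list with `pixels` (list of tile arrays) and `info`
#'   (data frame: `tile_id, patient_id, slide_id, x_origin, y_origin, label,
#'   resolution`). An empty mask yields an empty tile set.
#' @export
tessellate <- function(slide_image, roi_mask, tile_size = 512L,
                       min_roi_coverage = 0.5, slide_id = "slide",
                       patient_id = slide_id, label = NA_integer_,
                       resolution = 0.22) {
  assert_image(slide_image, "slide_image")
  d <- dim(slide_image)
  if (!is.matrix(roi_mask) || !all(dim(roi_mask) == d[1:2]))
    abort("roi_mask dimensions must equal slide_image dimensions")
  tile_size <- as.integer(tile_size)
  on_idx <- which(roi_mask != 0, arr.ind = TRUE)
  if (nrow(on_idx) == 0L) return(empty_tile_set())
  x0 <- min(on_idx[, 2]) - 1L  # ROI bounding-box top-left, 0-based
  y0 <- min(on_idx[, 1]) - 1L
  xs <- seq.int(x0, d[2] - tile_size, by = tile_size)
  ys <- seq.int(y0, d[1] - tile_size, by = tile_size)
  if (x0 > d[2] - tile_size) xs <- integer(0)
  if (y0 > d[1] - tile_size) ys <- integer(0)
  pixels <- list()
  rows <- list()
  for (y in ys) for (x in xs) {  # row-major: x fastest
    cell <- roi_mask[(y + 1):(y + tile_size), (x + 1):(x + tile_size)]
    if (mean(cell != 0) >= min_roi_coverage) {
      pixels[[length(pixels) + 1L]] <-
        slide_image[(y + 1):(y + tile_size), (x + 1):(x + tile_size), , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        tile_id = sprintf("%s_x%d_y%d", slide_id, x, y),
        patient_id = patient_id, slide_id = slide_id,
        x_origin = x, y_origin = y, label = label, resolution = resolution,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) return(empty_tile_set())
  tile_set(pixels, do.call(rbind, rows))
}

tile_set <- function(pixels, info) {
  structure(list(pixels = pixels, info = info), class = "tile_set")
}

empty_tile_set <- function() {
  tile_set(list(), data.frame(
    tile_id = character(0), patient_id = character(0), slide_id = character(0),
    x_origin = integer(0), y_origin = integer(0), label = integer(0),
    resolution = numeric(0), stringsAsFactors = FALSE
  ))
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile_set: %d tiles from %d slide(s)\n",
              length(x$pixels), length(unique(x$info$slide_id))))
  invisible(x)
}

#' Tile file-name convention
#'
#' Tiles are stored as `{slide_id}_x{X}_y{Y}.png`; `parse_tile_filename()`
#' inverts the convention.
#'
#' @param slide_id Slide identifier.
#' @param x,y Tile origin in slide pixels.
#' @return `tile_filename()`: a file name. `parse_tile_filename()`: a list
#'   with `slide_id`, `x`, `y`.
#' @export
tile_filename <- function(slide_id, x, y) {
  sprintf("%s_x%d_y%d.png", slide_id, as.integer(x), as.integer(y))
}

#' @rdname tile_filename
#' @param filename A file name produced by `tile_filename()`.
#' @export
parse_tile_filename <- function(filename) {
  base <- sub("\\.png$", "", basename(filename))
  m <- regmatches(base, regexec("^(.*)_x([0-9]+)_y([0-9]+)$", base))[[1]]
  if (length(m) != 4L) abort("file name does not follow {slide_id}_x{X}_y{Y}.png: ", filename)
  list(slide_id = m[2], x = as.integer(m[3]), y = as.integer(m[4]))
}

#' Write / read a tile set as PNG files plus a CSV manifest
#'
#' The round trip is lossless: PNG stores the 8-bit pixels exactly and the
#' manifest carries the metadata.
#'
#' @param tiles A `tile_set`.
#' @param dir Output directory (created if needed).
#' @return `write_tiles()`: path to the manifest CSV, invisibly.
#'   `read_tiles()`: a `tile_set`.
#' @export
write_tiles <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- tiles$info
  paths <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    fn <- tile_filename(info$slide_id[i], info$x_origin[i], info$y_origin[i])
    write_image_png(tiles$pixels[[i]], file.path(dir, fn))
    paths[i] <- fn
  }
  out <- data.frame(
    tile_path = paths,
    patient_id = info$patient_id, slide_id = info$slide_id,
    x_origin = info$x_origin, y_origin = info$y_origin, label = info$label,
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(out, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' @rdname write_tiles
#' @param manifest_path Path to a manifest CSV written by `write_tiles()` or
#'   [write_cohort()].
#' @export
read_tiles <- function(manifest_path) {
  if (!file.exists(manifest_path)) abort("manifest not found: ", manifest_path)
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  dir <- dirname(manifest_path)
  pixels <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- file.path(dir, man$tile_path[i])
    if (!file.exists(p)) abort("tile file missing: ", p)
    pixels[[i]] <- read_image_png(p)
  }
  info <- data.frame(
    tile_id = sprintf("%s_x%d_y%d", man$slide_id, man$x_origin, man$y_origin),
    patient_id = man$patient_id, slide_id = man$slide_id,
    x_origin = man$x_origin, y_origin = man$y_origin, label = man$label,
    resolution = 0.22, stringsAsFactors = FALSE
  )
  tile_set(pixels, info)
}
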