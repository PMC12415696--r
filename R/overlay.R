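# Whole-slide prediction overlay: tile-level scores mapped back to slide
# coordinates as a blue (score 0) -> red (score 1) heatmap, plus a GeoJSON
# export of one polygon per tile for slide viewers. Coordinates are
# full-resolution slide pixels, y increasing downward.

#' Build an overlay map from one slide's predictions
#'
#' @param preds Prediction data frame for a single slide (`slide_id,
#'   x_origin, y_origin, score`).
#' @param tile_size Tessellation tile size in pixels.
#' @return An `overlay_map`: list with `slide_id`, `tile_size`, and `cells`
#'   (data frame `x, y, score`).
#' @export
build_overlay <- function(preds, tile_size = 512L) {
  if (!nrow(preds)) {
    return(structure(list(slide_id = NA_character_, tile_size = as.integer(tile_size),
                          cells = data.frame(x = integer(0), y = integer(0),
                                             score = numeric(0))),
                     class = "overlay_map"))
  }
  if (length(unique(preds$slide_id)) != 1L)
    abort("all predictions must share one slide_id")
  if (any(preds$score < 0 | preds$score > 1)) abort("scores must lie in [0, 1]")
  key <- paste(preds$x_origin, preds$y_origin)
  if (anyDuplicated(key))
    abort("duplicate tile origin(s): ", paste(unique(key[duplicated(key)]), collapse = "; "))
  structure(
    list(slide_id = preds$slide_id[1], tile_size = as.integer(tile_size),
         cells = data.frame(x = as.integer(preds$x_origin),
                            y = as.integer(preds$y_origin),
                            score = preds$score)),
    class = "overlay_map"
  )
}

#' @export
print.overlay_map <- function(x, ...) {
  cat(sprintf("overlay_map: slide %s, %d cells of %d px\n",
              x$slide_id, nrow(x$cells), x$tile_size))
  invisible(x)
}

# linear blue -> red colormap; returns 0-255 RGB (round-half-up)
overlay_colour <- function(score) {
  cbind(r = round_half_up(255 * score), g = 0, b = round_half_up(255 * (1 - score)))
}

#' Render an overlay onto a slide image
#'
#' Each cell is tinted by linear interpolation between blue (score 0) and
#' red (score 1), alpha-blended onto the base image at the given opacity.
#' Pixels outside cells are untouched.
#'
#' @param map An `overlay_map`.
#' @param base `(h, w, 3)` RGB slide image covering all cells.
#' @param opacity Blend weight of the tint in `[0, 1]`.
#' @return `(h, w, 4)` RGBA array (alpha 255 everywhere).
#' @export
render_overlay <- function(map, base, opacity = 0.4) {
  assert_image(base, "base")
  d <- dim(base)
  ts <- map$tile_size
  if (nrow(map$cells) &&
      (max(map$cells$x) + ts > d[2] || max(map$cells$y) + ts > d[1]))
    abort("overlay cell exceeds the base image extent")
  out <- array(0, dim = c(d[1], d[2], 4L))
  out[, , 1:3] <- base
  out[, , 4] <- 255
  cols <- overlay_colour(map$cells$score)
  for (i in seq_len(nrow(map$cells))) {
    ys <- (map$cells$y[i] + 1):(map$cells$y[i] + ts)
    xs <- (map$cells$x[i] + 1):(map$cells$x[i] + ts)
    for (ch in 1:3)
      out[ys, xs, ch] <- round_half_up((1 - opacity) * out[ys, xs, ch] +
                                       opacity * cols[i, ch])
  }
  out
}

#' Export / import an overlay map as GeoJSON
#'
#' One Polygon feature per cell with a closed counter-clockwise ring over
#' the tile's half-open pixel extent and properties `prediction` and
#' `slide_id`. Coordinates are full-resolution pixels with y increasing
#' downward (stated in the document's top-level properties).
#'
#' @param map An `overlay_map`.
#' @param path Optional output file; if `NULL` the GeoJSON text is returned.
#' @return `export_geojson()`: the GeoJSON string (invisibly if written to
#'   `path`). `read_geojson()`: an `overlay_map`.
#' @export
export_geojson <- function(map, path = NULL) {
  ts <- map$tile_size
  features <- lapply(seq_len(nrow(map$cells)), function(i) {
    x <- map$cells$x[i]; y <- map$cells$y[i]
    ring <- list(c(x, y), c(x + ts, y), c(x + ts, y + ts), c(x, y + ts), c(x, y))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(prediction = map$cells$score[i], slide_id = map$slide_id)
    )
  })
  doc <- list(
    type = "FeatureCollection",
    properties = list(slide_id = map$slide_id, tile_size = ts,
                      coordinate_space = "pixel", y_axis = "down"),
    features = features
  )
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname export_geojson
#' @export
read_geojson <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection")) abort("not a FeatureCollection")
  ts <- as.integer(doc$properties$tile_size)
  cells <- do.call(rbind, lapply(doc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    data.frame(x = as.integer(ring[[1]][[1]]), y = as.integer(ring[[1]][[2]]),
               score = as.numeric(f$properties$prediction))
  }))
  slide_id <- if (length(doc$features)) doc$features[[1]]$properties$slide_id
              else doc$properties$slide_id
  structure(list(slide_id = slide_id, tile_size = ts,
                 cells = cells %||% data.frame(x = integer(0), y = integer(0),
                                               score = numeric(0))),
            class = "overlay_map")
}
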