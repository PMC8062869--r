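#' Write an element map as a multi-page TIFF with a JSON sidecar
#'
#' One 32-bit page per channel. TIFF float storage is portable only within
#' [0, 1], so each channel is min-max scaled on write and restored on read
#' from the per-channel ranges recorded in the sidecar (which also carries
#' the pixel size, channel order and provenance). A window with invalid
#' (unscanned) pixels gets one extra mask page.
#'
#' @param map An [element_map()].
#' @param path Output basename: writes `<path>.tif` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_element_map <- function(map, path) {
  stopifnot(inherits(map, "element_map"))
  win <- map$window
  pages <- list()
  ranges <- list()
  for (k in map$channels) {
    v <- map$values[[k]]
    v[is.na(v)] <- 0
    rg <- range(v)
    ranges[[k]] <- rg
    pages[[k]] <- if (diff(rg) > 0) (v - rg[1]) / diff(rg) else v * 0
  }
  has_mask <- !is.null(win$valid_mask)
  if (has_mask) pages$.valid_mask <- win$valid_mask * 1
  tiff::writeTIFF(unname(pages), paste0(path, ".tif"), bits.per.sample = 32L)
  jsonlite::write_json(
    list(pixel_size_um = win$pixel_size_um, width_px = win$width_px,
         height_px = win$height_px, channels = as.list(map$channels),
         ranges = ranges, has_valid_mask = has_mask,
         provenance = map$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an element map written by [write_element_map()]
#'
#' @param path Basename used at write time.
#' @return An [element_map()].
#' @export
read_element_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(path, ".tif"), all = TRUE)
  channels <- meta$channels
  vals <- list()
  for (i in seq_along(channels)) {
    k <- channels[i]
    rg <- meta$ranges[[k]]
    vals[[k]] <- pages[[i]] * (rg[2] - rg[1]) + rg[1]
  }
  valid <- NULL
  if (isTRUE(meta$has_valid_mask))
    valid <- pages[[length(channels) + 1]] > 0.5
  win <- obs_window(meta$width_px, meta$height_px, meta$pixel_size_um, valid)
  if (!is.null(valid)) for (k in channels) vals[[k]][!valid] <- NA_real_
  element_map(win, vals, provenance = meta$provenance %||% "")
}

#' Write / read a cell pattern as CSV
#'
#' Plain CSV with header `x_um,y_um,class`; window geometry goes to a JSON
#' sidecar so the pattern round-trips exactly.
#'
#' @param pattern A [cell_pattern()].
#' @param path Output basename: writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cell_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "cell_pattern"))
  df <- data.frame(x_um = pattern$x, y_um = pattern$y,
                   class = pattern$marks %||% rep("cell", n_points(pattern)))
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  win <- pattern$window
  jsonlite::write_json(
    list(pixel_size_um = win$pixel_size_um, width_px = win$width_px,
         height_px = win$height_px),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cell_pattern
#' @param window Optional [obs_window()]; read from the sidecar when absent.
#' @export
read_cell_pattern <- function(path, window = NULL) {
  df <- utils::read.csv(paste0(path, ".csv"))
  if (is.null(window)) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    window <- obs_window(meta$width_px, meta$height_px, meta$pixel_size_um)
  }
  cell_pattern(df$x_um, df$y_um, window,
               marks = if ("class" %in% names(df)) df$class else NULL)
}

#' Write / read a feature mask (label TIFF + classes CSV)
#'
#' Labels are stored as a 16-bit TIFF (scaled by 65535) with a
#' `feature_id,class` CSV and a JSON sidecar for the window geometry.
#'
#' @param mask A [feature_mask()].
#' @param path Output basename: writes `<path>.tif`, `<path>_classes.csv`,
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_mask <- function(mask, path) {
  stopifnot(inherits(mask, "feature_mask"))
  if (max(mask$labels) > 65535L) stop("more than 65535 features")
  tiff::writeTIFF(mask$labels / 65535, paste0(path, ".tif"),
                  bits.per.sample = 16L)
  utils::write.csv(data.frame(feature_id = as.integer(names(mask$classes)),
                              class = unname(mask$classes)),
                   paste0(path, "_classes.csv"), row.names = FALSE)
  win <- mask$window
  jsonlite::write_json(
    list(pixel_size_um = win$pixel_size_um, width_px = win$width_px,
         height_px = win$height_px),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_mask
#' @export
read_feature_mask <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  labels <- round(tiff::readTIFF(paste0(path, ".tif")) * 65535)
  storage.mode(labels) <- "integer"
  cls <- utils::read.csv(paste0(path, "_classes.csv"))
  win <- obs_window(meta$width_px, meta$height_px, meta$pixel_size_um)
  feature_mask(labels, stats::setNames(cls$class, cls$feature_id), win)
}

#' Read tile offsets exported from an image editor
#'
#' CSV with header `tile,offset_x_px,offset_y_px` (the per-tile placement
#' coordinates of the stitched panorama).
#'
#' @param path CSV path.
#' @return Data frame with columns `tile`, `offset_x_px`, `offset_y_px`.
#' @export
read_tile_offsets <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tile", "offset_x_px", "offset_y_px")
  if (!all(need %in% names(df)))
    stop("tile offset CSV must have columns tile,offset_x_px,offset_y_px")
  df[need]
}
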