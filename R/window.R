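#' Observation window for a stitched transect
#'
#' An observation window records the raster geometry shared by every stage of
#' the analysis: pixel dimensions, the physical pixel size in micrometres, and
#' (optionally) a logical mask of pixels that were actually scanned. All
#' spatial integrals (window area, quadrature weights, coverage percentages)
#' run over the valid region only, so a stitched panorama whose tiles do not
#' fill the bounding box is analysed over the scanned region, not the box.
#'
#' Coordinate convention (used package-wide): origin at the top-left corner,
#' x increases rightwards (columns), y increases downwards (rows); continuous
#' coordinates are in micrometres. Pixel `(i, j)` (row, column, 1-based) spans
#' the half-open rectangle `[(j-1)s, js) x [(i-1)s, is)` where `s` is
#' `pixel_size_um`, and its centre is `((j-0.5)s, (i-0.5)s)`.
#'
#' @param width_px,height_px Integer raster dimensions (columns, rows).
#' @param pixel_size_um Physical edge length of one pixel in micrometres.
#' @param valid_mask Optional logical matrix (`height_px` x `width_px`);
#'   `TRUE` marks scanned pixels. `NULL` means the whole rectangle is valid.
#' @return An object of class `obs_window`.
#' @examples
#' w <- obs_window(100, 100, pixel_size_um = 0.1)
#' window_area(w) # 100 um^2
#' @export
obs_window <- function(width_px, height_px, pixel_size_um, valid_mask = NULL) {
  stopifnot(width_px >= 1, height_px >= 1, pixel_size_um > 0)
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (!is.null(valid_mask)) {
    valid_mask <- as.matrix(valid_mask)
    storage.mode(valid_mask) <- "logical"
    if (nrow(valid_mask) != height_px || ncol(valid_mask) != width_px)
      stop("valid_mask dimensions must be height_px x width_px")
    if (!any(valid_mask)) stop("observation window has no valid pixels")
  }
  structure(
    list(width_px = width_px, height_px = height_px,
         pixel_size_um = pixel_size_um, valid_mask = valid_mask),
    class = "obs_window")
}

#' Area of the valid region of an observation window
#'
#' @param window An [obs_window()].
#' @return Area in square micrometres: (number of valid pixels) x
#'   `pixel_size_um^2`.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "obs_window"))
  n <- if (is.null(window$valid_mask)) window$width_px * window$height_px
       else sum(window$valid_mask)
  n * window$pixel_size_um^2
}

#' @export
print.obs_window <- function(x, ...) {
  cat(sprintf("Observation window: %d x %d px at %g um/px (area %.4g um^2)\n",
              x$width_px, x$height_px, x$pixel_size_um, window_area(x)))
  if (!is.null(x$valid_mask))
    cat(sprintf("  valid pixels: %d of %d\n", sum(x$valid_mask),
                length(x$valid_mask)))
  invisible(x)
}

# Map continuous um coordinates to (row, col) pixel indices. Points on the
# far boundary (x == width in um) are assigned to the last pixel so that a
# closed window does not reject its own corner points.
px_index <- function(window, x, y) {
  s <- window$pixel_size_um
  j <- pmin(floor(x / s) + 1L, window$width_px)
  i <- pmin(floor(y / s) + 1L, window$height_px)
  cbind(as.integer(i), as.integer(j))
}

# TRUE for points inside the window rectangle and on a valid pixel.
points_inside <- function(window, x, y) {
  s <- window$pixel_size_um
  inside <- x >= 0 & y >= 0 &
    x <= window$width_px * s & y <= window$height_px * s
  if (!is.null(window$valid_mask) && any(inside)) {
    ij <- px_index(window, x[inside], y[inside])
    inside[inside] <- window$valid_mask[ij]
  }
  inside
}

#' Multi-channel element map raster
#'
#' Container for per-element signal rasters (XEDS counts or quantified
#' weight-%) over a shared observation window. Channel units are arbitrary:
#' point-process fits standardise covariates internally, so detector counts
#' and weight-% behave identically downstream.
#'
#' @param window An [obs_window()].
#' @param values Named list of numeric matrices, one per element channel,
#'   each `height_px` x `width_px`. Names are element symbols and must be
#'   unique. Values must be finite on valid pixels (NA allowed outside).
#' @param provenance Optional free-text provenance note.
#' @return An object of class `element_map`.
#' @export
element_map <- function(window, values, provenance = "") {
  stopifnot(inherits(window, "obs_window"), is.list(values), length(values) >= 1)
  ch <- names(values)
  if (is.null(ch) || any(!nzchar(ch)) || anyDuplicated(ch))
    stop("channel names must be unique non-empty element symbols")
  for (k in ch) {
    v <- values[[k]]
    if (!is.matrix(v) || nrow(v) != window$height_px || ncol(v) != window$width_px)
      stop(sprintf("channel '%s' does not match the window dimensions", k))
    chk <- if (is.null(window$valid_mask)) v else v[window$valid_mask]
    if (any(!is.finite(chk)))
      stop(sprintf("channel '%s' has non-finite values on valid pixels", k))
  }
  structure(list(window = window, channels = ch, values = values,
                 provenance = provenance),
            class = "element_map")
}

#' @export
print.element_map <- function(x, ...) {
  cat(sprintf("Element map: %s | %d x %d px at %g um/px\n",
              paste(x$channels, collapse = ", "),
              x$window$width_px, x$window$height_px, x$window$pixel_size_um))
  invisible(x)
}

#' Planar point pattern of cell centroids
#'
#' @param x,y Numeric vectors of centroid coordinates in micrometres
#'   (image convention, see [obs_window()]).
#' @param window An [obs_window()]; every point must lie in its valid region.
#' @param marks Optional per-point morphology class (character or factor).
#' @return An object of class `cell_pattern` with components `x`, `y`,
#'   `marks`, `window`.
#' @export
cell_pattern <- function(x, y, window, marks = NULL) {
  stopifnot(inherits(window, "obs_window"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x)) {
    ok <- points_inside(window, x, y)
    if (!all(ok))
      stop(sprintf("%d point(s) outside the window's valid region (first: %s)",
                   sum(!ok), paste(which(!ok)[seq_len(min(5, sum(!ok)))],
                                   collapse = ", ")))
  }
  if (!is.null(marks)) {
    stopifnot(length(marks) == length(x))
    marks <- as.character(marks)
  }
  structure(list(x = x, y = y, marks = marks, window = window),
            class = "cell_pattern")
}

#' Number of points in a pattern
#' @param pattern A [cell_pattern()].
#' @return Integer point count.
#' @export
n_points <- function(pattern) length(pattern$x)

#' @export
print.cell_pattern <- function(x, ...) {
  cat(sprintf("Cell pattern: %d points in a %g x %g um window\n", n_points(x),
              x$window$width_px * x$window$pixel_size_um,
              x$window$height_px * x$window$pixel_size_um))
  if (!is.null(x$marks)) {
    tb <- table(x$marks)
    cat("  marks:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' Labelled raster of curated biofilm features
#'
#' @param labels Integer matrix (`height_px` x `width_px`); 0 is background,
#'   each positive value is one feature id.
#' @param classes Character vector naming each feature's class, `"cell"` or
#'   `"fungal"`, indexed by feature id (names are feature ids as strings, or
#'   a plain vector whose position is the feature id).
#' @param window An [obs_window()] with matching dimensions.
#' @return An object of class `feature_mask`.
#' @export
feature_mask <- function(labels, classes, window) {
  stopifnot(inherits(window, "obs_window"))
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (nrow(labels) != window$height_px || ncol(labels) != window$width_px)
    stop("label raster dimensions must equal window dimensions")
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(names(classes))) {
    if (length(ids) && max(ids) > length(classes))
      stop("classes vector shorter than the largest feature id")
    names(classes) <- as.character(seq_along(classes))
  }
  if (length(ids) && !all(as.character(ids) %in% names(classes)))
    stop("every feature id must have a class entry")
  bad <- setdiff(unique(as.character(classes)), c("cell", "fungal"))
  if (length(bad)) stop("feature classes must be 'cell' or 'fungal'")
  structure(list(labels = labels, classes = classes, window = window),
            class = "feature_mask")
}

#' @export
print.feature_mask <- function(x, ...) {
  ids <- unique(x$labels[x$labels > 0L])
  cls <- x$classes[as.character(ids)]
  cat(sprintf("Feature mask: %d features (%d cell, %d fungal) on %d x %d px\n",
              length(ids), sum(cls == "cell"), sum(cls == "fungal"),
              x$window$width_px, x$window$height_px))
  invisible(x)
}

#' Raster tile with a placement offset
#'
#' One SEM/XEDS acquisition tile, positioned on the panorama canvas by pixel
#' offsets (exported from the image editor used for stitching). Offsets may
#' be negative as long as the translated tile fits the canvas.
#'
#' @param values Named list of channel matrices (or a single matrix, taken
#'   as one unnamed channel `"value"`).
#' @param offset_x_px,offset_y_px Integer pixel offsets of the tile's
#'   top-left corner on the canvas (0 = flush with the canvas corner).
#' @return An object of class `raster_tile`.
#' @export
raster_tile <- function(values, offset_x_px = 0L, offset_y_px = 0L) {
  if (is.matrix(values)) values <- list(value = values)
  stopifnot(is.list(values), length(values) >= 1)
  if (is.null(names(values))) names(values) <- paste0("ch", seq_along(values))
  dims <- vapply(values, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels of a tile must share dimensions")
  structure(list(values = values, offset_x_px = as.integer(offset_x_px),
                 offset_y_px = as.integer(offset_y_px)),
            class = "raster_tile")
}
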