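#' 2D kernel density surface of cell centroids
#'
#' Gaussian product-kernel density of a point pattern on a regular grid over
#' the observation window, used to visualize biofilm hotspots. The default
#' per-axis bandwidth is the normal-reference rule
#' `h = 4 * 1.06 * min(sd, IQR/1.34) * n^(-1/5)` ([MASS::bandwidth.nrd()],
#' the convention of the plotting stack this analysis style grew out of);
#' as in [MASS::kde2d()], the Gaussian kernel standard deviation is `h/4`.
#' No edge correction is applied, so the surface is biased low within a
#' bandwidth of the transect border.
#'
#' @param pattern A [cell_pattern()] with at least one point.
#' @param bandwidth Optional numeric of length 1 or 2, `(h_x, h_y)` in
#'   micrometres. If any automatic bandwidth degenerates to 0 (e.g. all
#'   points coincident), it falls back to a pixel-scale floor
#'   (`4 * pixel_size_um`) with a warning.
#' @param grid_shape Integer grid dimensions `(nx, ny)` (default 128 x 128).
#' @param normalized If `TRUE` the surface integrates to 1; if `FALSE`
#'   (default) it is scaled to integrate to n, i.e. units of points per um^2.
#' @return An object of class `density_surface`: `window`, `x`, `y` (grid
#'   coordinates in um), `z` (matrix `length(x)` x `length(y)`), `bandwidth`,
#'   `normalized`, `n`.
#' @export
kde2d_cells <- function(pattern, bandwidth = NULL, grid_shape = c(128, 128),
                        normalized = FALSE) {
  stopifnot(inherits(pattern, "cell_pattern"))
  n <- n_points(pattern)
  if (n < 1) stop("kernel density estimation needs at least one point")
  win <- pattern$window
  lims <- c(0, win$width_px * win$pixel_size_um,
            0, win$height_px * win$pixel_size_um)
  if (is.null(bandwidth)) {
    h <- c(MASS::bandwidth.nrd(pattern$x), MASS::bandwidth.nrd(pattern$y))
    if (any(h <= 0) || any(!is.finite(h))) {
      warning("degenerate automatic bandwidth; falling back to pixel-scale floor")
      floor_h <- 4 * win$pixel_size_um
      h[h <= 0 | !is.finite(h)] <- floor_h
    }
  } else {
    h <- rep(as.numeric(bandwidth), length.out = 2)
    if (any(h <= 0)) stop("bandwidths must be positive")
  }
  grid_shape <- rep(as.integer(grid_shape), length.out = 2)
  kd <- MASS::kde2d(pattern$x, pattern$y, h = h, n = grid_shape, lims = lims)
  z <- kd$z
  if (!normalized) z <- z * n
  structure(list(window = win, x = kd$x, y = kd$y, z = z, bandwidth = h,
                 normalized = normalized, n = n),
            class = "density_surface")
}

#' Contour polylines of a density surface
#'
#' Contours at equally spaced density levels between the surface minimum and
#' maximum (interior levels only; the degenerate min/max levels are not
#' traced). A constant surface has no contours.
#'
#' @param surface A `density_surface` from [kde2d_cells()].
#' @param n_levels Number of levels (default 10).
#' @return List with one entry per non-empty level: `level` (density value)
#'   and `lines`, a list of data frames with `x`, `y` polyline vertices in
#'   micrometres.
#' @export
density_contours <- function(surface, n_levels = 10) {
  stopifnot(inherits(surface, "density_surface"), n_levels >= 1)
  zr <- range(surface$z)
  if (diff(zr) <= 0) return(list())
  levels <- seq(zr[1], zr[2], length.out = n_levels + 2L)[-c(1L, n_levels + 2L)]
  cl <- grDevices::contourLines(surface$x, surface$y, surface$z,
                                levels = levels)
  out <- lapply(unique(vapply(cl, `[[`, numeric(1), "level")), function(lv) {
    segs <- Filter(function(s) s$level == lv, cl)
    list(level = lv,
         lines = lapply(segs, function(s) data.frame(x = s$x, y = s$y)))
  })
  out
}

#' @export
print.density_surface <- function(x, ...) {
  cat(sprintf(
    "Density surface: %d x %d grid, bandwidth (%.3g, %.3g) um, %s\n",
    length(x$x), length(x$y), x$bandwidth[1], x$bandwidth[2],
    if (x$normalized) "normalized to 1" else sprintf("integrates to n = %d", x$n)))
  invisible(x)
}

#' Plot a density surface with optional contours over an element channel
#'
#' @param x A `density_surface`.
#' @param element Optional [element_map()] channel to underlay: give the map
#'   via `map` and the channel name via `element`.
#' @param map Optional [element_map()].
#' @param n_levels Contour level count (default 10).
#' @param ... Passed to [graphics::image()].
#' @export
plot.density_surface <- function(x, map = NULL, element = NULL,
                                 n_levels = 10, ...) {
  if (!is.null(map) && !is.null(element)) {
    win <- map$window
    s <- win$pixel_size_um
    v <- map$values[[element]]
    graphics::image(x = (seq_len(win$width_px) - 0.5) * s,
                    y = (seq_len(win$height_px) - 0.5) * s,
                    z = t(v), col = grDevices::hcl.colors(64, "Grays"),
                    xlab = "x (um)", ylab = "y (um)", useRaster = TRUE, ...)
  } else {
    graphics::image(x$x, x$y, x$z, col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "x (um)", ylab = "y (um)", useRaster = TRUE, ...)
  }
  cont <- density_contours(x, n_levels)
  for (lv in cont) for (ln in lv$lines)
    graphics::lines(ln$x, ln$y, col = "yellow")
  invisible(x)
}
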