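#' Stitch raster tiles into a panoramic element map
#'
#' Writes each tile onto the canvas at its recorded pixel offset, reproducing
#' the panorama assembled in the image editor from which offsets were
#' exported. Pixels covered by no tile are marked invalid in the panorama
#' window's `valid_mask` and are excluded from all downstream integrals.
#'
#' @param tiles List of [raster_tile()] objects, all sharing one channel set.
#' @param canvas An [obs_window()] giving the panorama dimensions and pixel
#'   size. Its own `valid_mask`, if any, is intersected with tile coverage.
#' @param overlap_rule How to resolve pixels covered by several tiles:
#'   `"last"` (default; tiles written in list order, later tiles win),
#'   `"first"`, or `"mean"`.
#' @return An [element_map()] over a window whose `valid_mask` marks covered
#'   pixels.
#' @examples
#' t1 <- raster_tile(matrix(1, 4, 4), 0, 0)
#' t2 <- raster_tile(matrix(2, 4, 4), 4, 0)
#' pan <- stitch_tiles(list(t1, t2), obs_window(8, 4, 1))
#' @export
stitch_tiles <- function(tiles, canvas,
                         overlap_rule = c("last", "first", "mean")) {
  overlap_rule <- match.arg(overlap_rule)
  stopifnot(inherits(canvas, "obs_window"), length(tiles) >= 1)
  tiles <- lapply(tiles, function(t) {
    if (inherits(t, "raster_tile")) t else raster_tile(t)
  })
  channels <- names(tiles[[1]]$values)
  for (k in seq_along(tiles)) {
    if (!identical(sort(names(tiles[[k]]$values)), sort(channels)))
      stop(sprintf("tile %d channel set differs from tile 1", k))
  }
  H <- canvas$height_px; W <- canvas$width_px
  acc <- lapply(channels, function(ch) matrix(NA_real_, H, W))
  names(acc) <- channels
  cover <- matrix(0L, H, W)
  for (k in seq_along(tiles)) {
    t <- tiles[[k]]
    th <- nrow(t$values[[1]]); tw <- ncol(t$values[[1]])
    rows <- (t$offset_y_px + 1L):(t$offset_y_px + th)
    cols <- (t$offset_x_px + 1L):(t$offset_x_px + tw)
    if (min(rows) < 1L || min(cols) < 1L || max(rows) > H || max(cols) > W)
      stop(sprintf("tile %d exceeds the canvas after translation", k))
    for (ch in channels) {
      v <- t$values[[ch]]
      if (overlap_rule == "last") {
        acc[[ch]][rows, cols] <- v
      } else if (overlap_rule == "first") {
        old <- acc[[ch]][rows, cols]
        acc[[ch]][rows, cols] <- ifelse(is.na(old), v, old)
      } else { # mean: accumulate sums, divide by coverage afterwards
        old <- acc[[ch]][rows, cols]
        acc[[ch]][rows, cols] <- ifelse(is.na(old), v, old + v)
      }
    }
    cover[rows, cols] <- cover[rows, cols] + 1L
  }
  if (overlap_rule == "mean") {
    for (ch in channels)
      acc[[ch]] <- ifelse(cover > 0L, acc[[ch]] / pmax(cover, 1L), NA_real_)
  }
  valid <- cover > 0L
  if (!is.null(canvas$valid_mask)) valid <- valid & canvas$valid_mask
  win <- obs_window(W, H, canvas$pixel_size_um,
                    valid_mask = if (all(valid)) NULL else valid)
  element_map(win, acc, provenance = sprintf("stitched from %d tile(s), overlap_rule=%s",
                                             length(tiles), overlap_rule))
}

#' Extract feature centroids from a labelled mask
#'
#' One point per feature of the requested class, at the arithmetic mean of
#' its pixel centres, converted to micrometres (pixel-centre convention: the
#' centre of pixel `(i, j)` is `((j-0.5)s, (i-0.5)s)`).
#'
#' @param mask A [feature_mask()].
#' @param class_filter `"cell"` (default), `"fungal"`, or `"all"`.
#' @return A [cell_pattern()] with the feature class as marks; empty pattern
#'   if no features match.
#' @export
mask_to_centroids <- function(mask, class_filter = c("cell", "fungal", "all")) {
  class_filter <- match.arg(class_filter)
  stopifnot(inherits(mask, "feature_mask"))
  win <- mask$window
  s <- win$pixel_size_um
  idx <- which(mask$labels > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(cell_pattern(numeric(0), numeric(0), win))
  id <- mask$labels[idx]
  keep_ids <- as.integer(names(mask$classes))[
    if (class_filter == "all") TRUE else mask$classes == class_filter]
  sel <- id %in% keep_ids
  if (!any(sel)) return(cell_pattern(numeric(0), numeric(0), win))
  idx <- idx[sel, , drop = FALSE]; id <- id[sel]
  cx <- tapply((idx[, 2] - 0.5) * s, id, mean)
  cy <- tapply((idx[, 1] - 0.5) * s, id, mean)
  ids <- as.integer(names(cx))
  cell_pattern(as.numeric(cx), as.numeric(cy), win,
               marks = unname(mask$classes[as.character(ids)]))
}

#' Rasterize a point pattern into per-pixel counts
#'
#' Utility raster used by density diagnostics: an integer raster whose sum
#' equals the number of points.
#'
#' @param pattern A [cell_pattern()].
#' @param window Optional [obs_window()] to rasterize onto (defaults to the
#'   pattern's own window). Points falling outside it raise an error naming
#'   the offending indices.
#' @return Integer matrix of per-pixel point counts.
#' @export
rasterize_points <- function(pattern, window = NULL) {
  stopifnot(inherits(pattern, "cell_pattern"))
  if (is.null(window)) window <- pattern$window
  stopifnot(inherits(window, "obs_window"))
  counts <- matrix(0L, window$height_px, window$width_px)
  if (!n_points(pattern)) return(counts)
  ok <- points_inside(window, pattern$x, pattern$y)
  if (!all(ok))
    stop(sprintf("point(s) outside window: %s",
                 paste(which(!ok), collapse = ", ")))
  ij <- px_index(window, pattern$x, pattern$y)
  lin <- (ij[, 2] - 1L) * window$height_px + ij[, 1]
  tab <- tabulate(lin, nbins = length(counts))
  counts[] <- as.integer(tab)
  counts
}

#' Label connected components of a binary raster (8-connected)
#'
#' Two-pass union-find labelling with 8-connectivity, for turning a painted
#' binary feature layer into a labelled mask when per-feature ids are not
#' supplied. Touching features that already carry distinct labels elsewhere
#' in the pipeline are never merged; this is only for raw binary input.
#'
#' @param binary Logical or 0/1 matrix.
#' @return Integer matrix of feature labels (0 background, 1..k features).
#' @export
label_components <- function(binary) {
  b <- as.matrix(binary)
  storage.mode(b) <- "logical"
  H <- nrow(b); W <- ncol(b)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!b[i, j]) next
    # neighbours already visited in column-major order: left column trio + above
    nb <- integer(0)
    if (i > 1L && lab[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
    if (j > 1L) {
      if (lab[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
      if (i > 1L && lab[i - 1L, j - 1L]) nb <- c(nb, lab[i - 1L, j - 1L])
      if (i < H && lab[i + 1L, j - 1L]) nb <- c(nb, lab[i + 1L, j - 1L])
    }
    if (!length(nb)) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      r <- min(roots)
      lab[i, j] <- r
      for (q in roots) parent[q] <- r
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  pos <- lab > 0L
  lab[pos] <- relab[lab[pos]]
  lab
}
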