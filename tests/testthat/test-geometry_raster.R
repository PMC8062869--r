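test_that("window area counts valid pixels only", {
  w <- obs_window(100, 100, 0.1)
  expect_equal(window_area(w), 100)
  vm <- matrix(TRUE, 100, 100); vm[1:50, ] <- FALSE
  expect_equal(window_area(obs_window(100, 100, 0.1, vm)), 50)
  expect_error(obs_window(10, 10, 0.1, matrix(FALSE, 10, 10)), "no valid")
})

test_that("stitching reproduces single and disjoint tiles verbatim", {
  t1 <- raster_tile(matrix(1:16, 4, 4), 0, 0)
  pan <- stitch_tiles(list(t1), obs_window(4, 4, 1))
  expect_identical(pan$values[[1]], matrix(as.numeric(1:16), 4, 4))
  expect_null(pan$window$valid_mask) # all covered

  t2 <- raster_tile(matrix(2, 4, 4), 4, 0)
  pan2 <- stitch_tiles(list(raster_tile(matrix(1, 4, 4), 0, 0), t2),
                       obs_window(8, 4, 1))
  expect_equal(pan2$values[[1]][, 1:4], matrix(1, 4, 4))
  expect_equal(pan2$values[[1]][, 5:8], matrix(2, 4, 4))
  expect_null(pan2$window$valid_mask)
})

test_that("overlap rules resolve shared pixels as last-wins or mean", {
  a <- raster_tile(matrix(1, 4, 4), 0, 0)
  b <- raster_tile(matrix(2, 4, 4), 3, 0) # overlap on canvas column 4
  last <- stitch_tiles(list(a, b), obs_window(7, 4, 1))
  expect_equal(last$values[[1]][, 4], rep(2, 4))
  avg <- stitch_tiles(list(a, b), obs_window(7, 4, 1), overlap_rule = "mean")
  expect_equal(avg$values[[1]][, 4], rep(1.5, 4))
  expect_equal(avg$values[[1]][, 1], rep(1, 4))
  expect_equal(avg$values[[1]][, 7], rep(2, 4))
})

test_that("uncovered canvas pixels are invalid and stitching is idempotent", {
  t1 <- raster_tile(matrix(runif(12), 3, 4), 1, 1)
  pan <- stitch_tiles(list(t1), obs_window(6, 5, 1))
  expect_equal(sum(pan$window$valid_mask), 12)
  expect_equal(window_area(pan$window), 12)
  # restitching the panorama as one full tile reproduces it bit-exactly
  vals <- pan$values[[1]]
  vals[is.na(vals)] <- 0
  pan2 <- stitch_tiles(list(raster_tile(vals, 0, 0)),
                       obs_window(6, 5, 1, pan$window$valid_mask))
  expect_identical(pan2$values[[1]][pan2$window$valid_mask],
                   pan$values[[1]][pan$window$valid_mask])
  expect_identical(pan2$window$valid_mask, pan$window$valid_mask)
})

test_that("stitching rejects mismatched channels and out-of-canvas tiles", {
  a <- raster_tile(list(Fe = matrix(1, 2, 2)), 0, 0)
  b <- raster_tile(list(S = matrix(1, 2, 2)), 2, 0)
  expect_error(stitch_tiles(list(a, b), obs_window(4, 2, 1)), "channel")
  c <- raster_tile(matrix(1, 3, 3), 2, 0)
  expect_error(stitch_tiles(list(c), obs_window(4, 4, 1)), "tile 1")
})

test_that("centroids are pixel-centre means in micrometres", {
  # 2x2 square occupying pixels (0,0)-(1,1) -> centroid (1, 1)
  lab <- matrix(0L, 4, 4); lab[1:2, 1:2] <- 1L
  m <- feature_mask(lab, c("1" = "cell"), obs_window(4, 4, 1))
  p <- mask_to_centroids(m)
  expect_equal(c(p$x, p$y), c(1, 1))

  # L-shaped 3-pixel feature {(0,0),(1,0),(0,1)} -> (5/6, 5/6)
  lab <- matrix(0L, 3, 3); lab[1, 1] <- 1L; lab[1, 2] <- 1L; lab[2, 1] <- 1L
  p <- mask_to_centroids(feature_mask(lab, c("1" = "cell"), obs_window(3, 3, 1)))
  expect_equal(c(p$x, p$y), c(5 / 6, 5 / 6))

  # empty mask -> empty pattern
  p <- mask_to_centroids(feature_mask(matrix(0L, 3, 3), character(0),
                                      obs_window(3, 3, 1)))
  expect_equal(n_points(p), 0)
})

test_that("centroids of isolated single-pixel features are the seeded centres", {
  withr::with_seed(42, {
    w <- obs_window(40, 40, 0.5)
    lab <- matrix(0L, 40, 40)
    ij <- cbind(sample(2:39, 12), sample(2:39, 12))
    ij <- ij[!duplicated(ij), , drop = FALSE]
    lab[ij] <- seq_len(nrow(ij))
    cls <- stats::setNames(rep("cell", nrow(ij)), seq_len(nrow(ij)))
    p <- mask_to_centroids(feature_mask(lab, cls, w))
    ord <- order(p$x, p$y)
    exp_x <- (ij[, 2] - 0.5) * 0.5; exp_y <- (ij[, 1] - 0.5) * 0.5
    ord2 <- order(exp_x, exp_y)
    expect_equal(p$x[ord], exp_x[ord2])
    expect_equal(p$y[ord], exp_y[ord2])
  })
})

test_that("class filter selects cell vs fungal centroids", {
  lab <- matrix(0L, 4, 6); lab[1, 1] <- 1L; lab[3, 5] <- 2L
  m <- feature_mask(lab, c("1" = "cell", "2" = "fungal"), obs_window(6, 4, 1))
  expect_equal(n_points(mask_to_centroids(m, "cell")), 1)
  expect_equal(n_points(mask_to_centroids(m, "fungal")), 1)
  expect_equal(n_points(mask_to_centroids(m, "all")), 2)
})

test_that("rasterized point counts sum to n and stack coincident points", {
  w <- obs_window(10, 10, 1)
  p <- cell_pattern(c(0.5, 3.2, 7.7), c(0.5, 4.1, 9.9), w)
  r <- rasterize_points(p)
  expect_equal(sum(r), 3)
  p2 <- cell_pattern(c(2.5, 2.5), c(2.5, 2.5), w)
  expect_equal(max(rasterize_points(p2)), 2)
  # property: sum equals n for random patterns
  for (seed in 1:5) {
    pr <- withr::with_seed(seed, cell_pattern(runif(50, 0, 10),
                                              runif(50, 0, 10), w))
    expect_equal(sum(rasterize_points(pr)), 50)
  }
  expect_error(rasterize_points(p, obs_window(5, 5, 1)), "outside")
})

test_that("pixel/um round trip moves coordinates by less than one pixel", {
  w <- obs_window(37, 53, 0.17)
  withr::with_seed(3, {
    x <- runif(100, 0, 37 * 0.17); y <- runif(100, 0, 53 * 0.17)
    ij <- biofilmspat:::px_index(w, x, y)
    xc <- (ij[, 2] - 0.5) * 0.17; yc <- (ij[, 1] - 0.5) * 0.17
    expect_true(all(abs(xc - x) < 0.17 & abs(yc - y) < 0.17))
  })
})

test_that("8-connected labelling joins diagonals; components are separated", {
  b <- matrix(FALSE, 5, 5); b[2, 2] <- TRUE; b[3, 3] <- TRUE; b[5, 5] <- TRUE
  lab <- label_components(b)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[2, 2])
  expect_equal(max(label_components(matrix(FALSE, 3, 3))), 0)
})

test_that("element maps, patterns and masks round-trip through files", {
  dir <- withr::local_tempdir()
  w <- obs_window(20, 15, 0.25)
  withr::with_seed(8, {
    vals <- list(Fe = matrix(runif(300, 0, 40), 15, 20),
                 S = matrix(runif(300, -3, 7), 15, 20))
  })
  m <- element_map(w, vals, provenance = "fixture")
  write_element_map(m, file.path(dir, "map"))
  m2 <- read_element_map(file.path(dir, "map"))
  expect_equal(m2$channels, m$channels)
  expect_equal(m2$values$Fe, m$values$Fe, tolerance = 1e-6)
  expect_equal(m2$values$S, m$values$S, tolerance = 1e-6)
  expect_equal(m2$window$pixel_size_um, 0.25)

  p <- cell_pattern(c(0.3, 2.2), c(1.1, 3.3), w, marks = c("cell", "cell"))
  write_cell_pattern(p, file.path(dir, "cells"))
  p2 <- read_cell_pattern(file.path(dir, "cells"))
  expect_equal(p2$x, p$x)
  expect_equal(p2$y, p$y)

  lab <- matrix(0L, 15, 20); lab[2:3, 2:3] <- 1L; lab[10, 10] <- 2L
  mk <- feature_mask(lab, c("1" = "cell", "2" = "fungal"), w)
  write_feature_mask(mk, file.path(dir, "mask"))
  mk2 <- read_feature_mask(file.path(dir, "mask"))
  expect_identical(mk2$labels, mk$labels)
  expect_equal(unname(mk2$classes), unname(mk$classes))

  off <- data.frame(tile = c("a", "b"), offset_x_px = c(0L, 4L),
                    offset_y_px = c(0L, 0L))
  f <- file.path(dir, "offsets.csv")
  utils::write.csv(off, f, row.names = FALSE)
  expect_equal(read_tile_offsets(f)$offset_x_px, c(0L, 4L))
})
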