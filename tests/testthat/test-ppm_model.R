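test_that("quadrature weights partition the window area", {
  w <- obs_window(100, 100, 0.01) # unit-area window
  empty <- cell_pattern(numeric(0), numeric(0), w)
  q <- build_quadrature(empty, w, dummy_spacing_um = 0.1) # 10 x 10 tiles
  expect_equal(length(q$w), 100)
  expect_equal(unname(q$w), rep(0.01, 100))
  expect_equal(sum(q$w), 1)

  # conservation holds for any pattern and spacing, and on masked windows
  for (seed in 1:3) {
    p <- withr::with_seed(seed, cell_pattern(runif(40), runif(40), w))
    q2 <- build_quadrature(p, dummy_spacing_um = runif(1, 0.05, 0.3))
    expect_equal(sum(q2$w), window_area(w), tolerance = 1e-9)
    expect_equal(sum(q2$is_data), 40)
  }
  vm <- matrix(TRUE, 100, 100); vm[1:40, ] <- FALSE
  wm <- obs_window(100, 100, 0.01, vm)
  qm <- build_quadrature(cell_pattern(0.5, 0.9, wm), wm,
                         dummy_spacing_um = 0.13)
  expect_equal(sum(qm$w), window_area(wm), tolerance = 1e-9)
})

test_that("a data point sharing a tile with its dummy splits the tile area", {
  w <- obs_window(10, 10, 0.1) # 1 um^2, single tile
  p <- cell_pattern(0.3, 0.3, w)
  q <- build_quadrature(p, w, dummy_spacing_um = 1)
  expect_equal(length(q$w), 2)
  expect_equal(unname(q$w), c(0.5, 0.5))
})

test_that("the default dummy grid is at least 64x64 and 4x the data size", {
  w <- obs_window(200, 200, 0.1)
  p <- withr::with_seed(1, cell_pattern(runif(2000, 0, 20), runif(2000, 0, 20), w))
  q <- build_quadrature(p)
  expect_gte(sum(!q$is_data), 4 * 2000 * 0.9) # a few tiles may merge points
  q2 <- build_quadrature(cell_pattern(1, 1, w))
  expect_equal(c(q2$nx, q2$ny), c(64, 64))
})

test_that("the null model recovers the homogeneous MLE log(n/|W|)", {
  w <- obs_window(100, 100, 0.01)
  p <- withr::with_seed(7, cell_pattern(runif(100), runif(100), w))
  f <- fit_ppm(p, NULL)
  expect_equal(unname(f$beta[1]), log(100), tolerance = 1e-8)
  expect_true(f$converged)
  # fitted intensity integrates back to n
  expect_equal(sum(f$fitted_intensity) * 0.01^2, 100, tolerance = 1e-6)
  expect_true(all(f$fitted_intensity >= 0))
})

test_that("constant covariates are dropped and reduce to the null fit", {
  w <- obs_window(80, 80, 0.1)
  p <- withr::with_seed(3, cell_pattern(runif(60, 0, 8), runif(60, 0, 8), w))
  m <- element_map(w, list(Fe = matrix(7, 80, 80)))
  q <- build_quadrature(p)
  expect_warning(f1 <- fit_ppm(p, m, quad = q), "constant covariate")
  f0 <- fit_ppm(p, NULL, quad = q)
  expect_equal(f1$loglik, f0$loglik)
  expect_equal(f1$dropped, "Fe")
})

test_that("log-likelihood is monotone under nesting and the LRT is coherent", {
  sc <- selection_scene(17)
  m <- make_element_map(sc)
  p <- simulate_selective_cells(m, beta = c(S = 1), target_n = 250, seed = 5)
  q <- build_quadrature(p)
  f0 <- fit_ppm(p, NULL, quad = q, keep_raster = FALSE)
  f1 <- fit_ppm(p, m, quad = q, channels = "S", keep_raster = FALSE)
  f2 <- fit_ppm(p, m, quad = q, channels = c("S", "Fe"), keep_raster = FALSE)
  expect_gte(f1$loglik, f0$loglik)
  expect_gte(f2$loglik, f1$loglik)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_equal(lrt$stat, 2 * (f1$loglik - f0$loglik))
  expect_equal(lrt$stat, f0$deviance - f1$deviance, tolerance = 1e-6)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$p_value,
               stats::pchisq(lrt$stat, 1, lower.tail = FALSE))
  # model against itself: stat 0, p 1
  self <- likelihood_ratio_test(f1, f1)
  expect_equal(self$stat, 0)
  expect_equal(self$p_value, 1)
  # non-nested models are rejected
  fFe <- fit_ppm(p, m, quad = q, channels = "Fe", keep_raster = FALSE)
  expect_error(likelihood_ratio_test(f1, fFe), "not nested")
})

test_that("planted coefficients are recovered within 3 standard errors", {
  sc <- grain_scene(width_px = 250, height_px = 384, seed = 23)
  m <- make_element_map(sc)
  p <- simulate_selective_cells(m, beta = c(S = 1.5), target_n = 500, seed = 41)
  f <- fit_ppm(p, m, channels = "S")
  expect_lt(abs(f$beta[["S"]] - 1.5), 3 * f$se[["S"]])
  expect_true(f$converged)
  # raw-scale slope is the standardized slope over the channel sd
  expect_equal(unname(f$beta_raw["S"]),
               unname(f$beta["S"] / f$standardization$scale["S"]))
})

test_that("the LRT is invariant to affine rescaling of covariates", {
  sc <- selection_scene(29)
  m <- make_element_map(sc)
  p <- simulate_selective_cells(m, beta = c(S = 1), target_n = 200, seed = 13)
  q <- build_quadrature(p)
  m2 <- element_map(m$window, lapply(m$values, function(v) 1000 * v + 50))
  f0 <- fit_ppm(p, NULL, quad = q, keep_raster = FALSE)
  a <- likelihood_ratio_test(f0, fit_ppm(p, m, quad = q, channels = "S",
                                         keep_raster = FALSE))
  b <- likelihood_ratio_test(f0, fit_ppm(p, m2, quad = q, channels = "S",
                                         keep_raster = FALSE))
  expect_equal(a$stat, b$stat, tolerance = 1e-6)
})

test_that("model search is exhaustive, ranked by the selection rule, and flags sparse patterns", {
  sc <- selection_scene(37)
  m <- make_element_map(sc)
  p <- simulate_selective_cells(m, beta = c(S = 1.5), target_n = 300, seed = 19)
  sr <- model_search(p, m)
  expect_equal(nrow(sr$rows), sum(choose(5, 1:5))) # all 31 subsets
  expect_named(sr$rows, c("model", "n_covariates", "df", "p_value", "log_p",
                          "deviance", "converged"))
  expect_true(all(sr$rows$deviance >= 0))
  expect_true(!is.unsorted(sr$rows$log_p))
  expect_true(sr$min_cells_ok)
  expect_true("S" %in% sr$best)

  sparse <- simulate_selective_cells(m, beta = c(S = 1.5), target_n = 40,
                                     seed = 19)
  sr2 <- model_search(sparse, m)
  expect_false(sr2$min_cells_ok)

  row <- search_report_row(sr, coupon = "D1T6", substrate = "Homestake")
  expect_named(row, c("substrate", "coupon", "model", "p_value", "deviance"))
  expect_error(model_search(p, m, max_fits = 10), "pre-select")
})
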