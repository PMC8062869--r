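#' Berman-Turner quadrature scheme for Poisson point-process likelihoods
#'
#' Discretizes the intensity integral of the inhomogeneous Poisson
#' log-likelihood `sum_i log lambda(x_i) - integral_W lambda(u) du` so that
#' maximum-likelihood fitting becomes a weighted Poisson count regression.
#' Dummy points are laid on a regular grid of tiles over the valid region;
#' each tile's valid area is split equally among the data and dummy points
#' it contains, so the weights sum exactly to the window area.
#'
#' The default tile grid has at least 64 x 64 tiles and at least four times
#' as many dummy points as data points.
#'
#' @param pattern A [cell_pattern()].
#' @param window Window to build the scheme on (defaults to the pattern's).
#' @param dummy_spacing_um Optional tile edge length in micrometres;
#'   overrides the default grid resolution.
#' @return An object of class `quad_scheme`: vectors `x`, `y`, `is_data`,
#'   `w` (weights in um^2), plus `window` and the tile grid description.
#' @examples
#' w <- obs_window(100, 100, 0.1)
#' q <- build_quadrature(cell_pattern(numeric(0), numeric(0), w), w,
#'                       dummy_spacing_um = 1)
#' sum(q$w) == window_area(w)
#' @export
build_quadrature <- function(pattern, window = NULL, dummy_spacing_um = NULL) {
  stopifnot(inherits(pattern, "cell_pattern"))
  if (is.null(window)) window <- pattern$window
  stopifnot(inherits(window, "obs_window"))
  s <- window$pixel_size_um
  Wum <- window$width_px * s
  Hum <- window$height_px * s
  n <- n_points(pattern)
  if (is.null(dummy_spacing_um)) {
    m <- max(64L, ceiling(sqrt(4 * max(n, 1L))))
    nx <- m; ny <- m
  } else {
    stopifnot(dummy_spacing_um > 0, dummy_spacing_um <= max(Wum, Hum))
    nx <- max(1L, ceiling(Wum / dummy_spacing_um))
    ny <- max(1L, ceiling(Hum / dummy_spacing_um))
  }
  # a tile narrower than one pixel would have zero valid area
  nx <- min(nx, window$width_px)
  ny <- min(ny, window$height_px)
  sx <- Wum / nx; sy <- Hum / ny
  tile_of <- function(x, y) {
    tx <- pmin(floor(x / sx) + 1L, nx)
    ty <- pmin(floor(y / sy) + 1L, ny)
    (tx - 1L) * ny + ty
  }
  # valid area per tile from pixel centres
  if (is.null(window$valid_mask)) {
    pix_ij <- NULL
    # all pixels valid: compute per-tile pixel counts analytically by binning
    cx <- (seq_len(window$width_px) - 0.5) * s
    cy <- (seq_len(window$height_px) - 0.5) * s
    tx <- pmin(floor(cx / sx) + 1L, nx)
    ty <- pmin(floor(cy / sy) + 1L, ny)
    cnt_x <- tabulate(tx, nx)
    cnt_y <- tabulate(ty, ny)
    tile_px <- as.vector(outer(cnt_y, cnt_x)) # ty fastest, matches tile id
    tile_area <- tile_px * s^2
  } else {
    idx <- which(window$valid_mask, arr.ind = TRUE)
    pcx <- (idx[, 2] - 0.5) * s
    pcy <- (idx[, 1] - 0.5) * s
    tid <- tile_of(pcx, pcy)
    tile_area <- tabulate(tid, nx * ny) * s^2
  }
  # one dummy point per non-empty tile, at the tile centre when that pixel
  # is valid, else at the first valid pixel centre in the tile
  keep <- which(tile_area > 0)
  tcx <- ((ceiling(keep / ny) - 1L) + 0.5) * sx
  tcy <- (((keep - 1L) %% ny) + 0.5) * sy
  if (!is.null(window$valid_mask)) {
    ok <- points_inside(window, tcx, tcy)
    if (any(!ok)) {
      first_px <- tapply(seq_len(nrow(idx)), tid, function(v) v[1])
      repl <- first_px[as.character(keep[!ok])]
      tcx[!ok] <- pcx[repl]
      tcy[!ok] <- pcy[repl]
    }
  }
  if (n > 0) {
    ok <- points_inside(window, pattern$x, pattern$y)
    if (!all(ok))
      stop(sprintf("data point(s) on invalid pixels: %s",
                   paste(which(!ok), collapse = ", ")))
  }
  qx <- c(pattern$x, tcx)
  qy <- c(pattern$y, tcy)
  is_data <- c(rep(TRUE, n), rep(FALSE, length(tcx)))
  tq <- tile_of(qx, qy)
  cnt <- tabulate(tq, nx * ny)
  w <- tile_area[tq] / cnt[tq]
  structure(list(x = qx, y = qy, is_data = is_data, w = w, window = window,
                 nx = nx, ny = ny, spacing_um = c(sx, sy)),
            class = "quad_scheme")
}

#' @export
print.quad_scheme <- function(x, ...) {
  cat(sprintf(
    "Quadrature: %d data + %d dummy points (%d x %d tiles), total weight %.6g um^2\n",
    sum(x$is_data), sum(!x$is_data), x$nx, x$ny, sum(x$w)))
  invisible(x)
}

# Covariate design at quadrature points: standardized raster values plus the
# standardization statistics over valid pixels.
ppm_design <- function(elements, quad, channels = NULL) {
  if (is.null(elements)) {
    return(list(X = matrix(numeric(0), length(quad$x), 0,
                           dimnames = list(NULL, character(0))),
                channels = character(0),
                center = numeric(0), scale = numeric(0)))
  }
  stopifnot(inherits(elements, "element_map"))
  if (is.null(channels)) channels <- elements$channels
  stopifnot(all(channels %in% elements$channels))
  win <- elements$window
  ij <- px_index(win, quad$x, quad$y)
  center <- scale <- numeric(length(channels))
  names(center) <- names(scale) <- channels
  X <- matrix(NA_real_, length(quad$x), length(channels),
              dimnames = list(NULL, channels))
  for (k in channels) {
    v <- elements$values[[k]]
    px <- if (is.null(win$valid_mask)) as.vector(v) else v[win$valid_mask]
    center[k] <- mean(px)
    scale[k] <- stats::sd(px)
    X[, k] <- v[ij]
  }
  list(X = X, channels = channels, center = center, scale = scale)
}

# Core weighted-Poisson engine shared by fit_ppm and model_search. X excludes
# the intercept; columns are already standardized.
ppm_engine <- function(Xs, z, w, maxit = 100, epsilon = 1e-8) {
  XX <- cbind(`(Intercept)` = 1, Xs)
  y <- z / w
  fit <- suppressWarnings(stats::glm.fit(
    XX, y, weights = w, family = stats::quasipoisson(),
    control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  beta <- fit$coefficients
  aliased <- is.na(beta)
  beta[aliased] <- 0
  eta <- drop(XX %*% beta)
  lam <- exp(eta)
  loglik <- sum(eta[z == 1]) - sum(w * lam)
  # Fisher information of the Poisson process likelihood at the estimate
  Xk <- XX[, !aliased, drop = FALSE]
  info <- crossprod(Xk * sqrt(w * lam))
  se <- rep(NA_real_, length(beta))
  ok <- !aliased
  se[ok] <- tryCatch(sqrt(diag(solve(info))), error = function(e) NA_real_)
  names(se) <- names(beta)
  list(beta = beta, se = se, aliased = aliased, loglik = loglik,
       deviance = fit$deviance, rank = fit$rank, converged = fit$converged,
       lambda_quad = lam)
}

#' Fit an inhomogeneous Poisson point-process model
#'
#' Maximum-likelihood fit of the log-linear intensity
#' `lambda(u) = exp(beta0 + sum_k beta_k Z_k(u))` to a cell pattern, where
#' the `Z_k` are element-map channels. The likelihood is discretized by
#' Berman-Turner quadrature ([build_quadrature()]) and maximized by
#' iteratively reweighted least squares on the equivalent weighted Poisson
#' count regression. Covariates are standardized internally (zero mean, unit
#' variance over valid pixels): `beta` is reported on the standardized scale
#' (unit-free, comparable across detector-unit conventions) and `beta_raw`
#' on the original channel scale.
#'
#' @param pattern A [cell_pattern()] with at least one point.
#' @param covariates An [element_map()] or `NULL` for the null
#'   (homogeneous) model.
#' @param quad A `quad_scheme`; built with defaults when omitted. Reuse one
#'   scheme across nested fits so likelihoods are comparable.
#' @param channels Channel subset to use (default: all channels of
#'   `covariates`).
#' @param keep_raster If `TRUE` (default) the fitted intensity raster is
#'   computed over the window.
#' @param smooth_sigma_px Optional Gaussian pre-smoothing of covariate
#'   rasters (standard deviation in pixels, default 0 = off).
#' @param maxit,epsilon IRLS iteration cap (default 100) and relative
#'   convergence tolerance (default 1e-8).
#' @return An object of class `ppm_fit`: `covariate_names`, `beta`, `se`
#'   (standardized scale), `beta_raw`, `loglik`, `deviance`, `converged`,
#'   `n_data`, `fitted_intensity` (points per um^2; NA off the valid
#'   region), `dropped` (channels removed as constant/collinear), `quad`.
#' @export
fit_ppm <- function(pattern, covariates = NULL, quad = NULL, channels = NULL,
                    keep_raster = TRUE, smooth_sigma_px = 0,
                    maxit = 100, epsilon = 1e-8) {
  stopifnot(inherits(pattern, "cell_pattern"))
  if (n_points(pattern) < 1) stop("cannot fit a point-process model to an empty pattern")
  if (is.null(quad)) quad <- build_quadrature(pattern)
  stopifnot(inherits(quad, "quad_scheme"))
  if (!is.null(covariates) && smooth_sigma_px > 0)
    covariates <- smooth_element_map(covariates, smooth_sigma_px)
  des <- ppm_design(covariates, quad, channels)
  # drop constant channels before fitting
  const <- des$channels[des$scale == 0 | !is.finite(des$scale)]
  use <- setdiff(des$channels, const)
  if (length(const))
    warning(sprintf("constant covariate(s) dropped: %s",
                    paste(const, collapse = ", ")))
  Xs <- sweep(sweep(des$X[, use, drop = FALSE], 2, des$center[use]),
              2, des$scale[use], `/`)
  z <- as.numeric(quad$is_data)
  eng <- ppm_engine(Xs, z, quad$w, maxit = maxit, epsilon = epsilon)
  aliased_ch <- use[eng$aliased[-1]]
  if (length(aliased_ch))
    warning(sprintf("collinear covariate(s) dropped: %s",
                    paste(aliased_ch, collapse = ", ")))
  kept <- setdiff(use, aliased_ch)
  beta <- eng$beta
  beta_raw <- beta
  if (length(use)) {
    beta_raw[-1] <- beta[-1] / des$scale[use]
    beta_raw[1] <- beta[1] - sum(beta[-1] * des$center[use] / des$scale[use])
  }
  fitted_intensity <- NULL
  if (keep_raster) {
    win <- quad$window
    eta <- matrix(beta[1], win$height_px, win$width_px)
    for (k in seq_along(use))
      eta <- eta + beta[k + 1] *
        (covariates$values[[use[k]]] - des$center[use[k]]) / des$scale[use[k]]
    fitted_intensity <- exp(eta)
    if (!is.null(win$valid_mask)) fitted_intensity[!win$valid_mask] <- NA_real_
  }
  structure(list(
    covariate_names = kept, beta = beta, se = eng$se, beta_raw = beta_raw,
    loglik = eng$loglik, deviance = eng$deviance, rank = eng$rank,
    converged = eng$converged, n_data = sum(quad$is_data),
    dropped = c(const, aliased_ch), fitted_intensity = fitted_intensity,
    standardization = list(center = des$center[use], scale = des$scale[use]),
    quad = quad), class = "ppm_fit")
}

#' @export
print.ppm_fit <- function(x, ...) {
  cat(sprintf("Poisson point-process model (%s), n = %d\n",
              if (length(x$covariate_names))
                paste(x$covariate_names, collapse = " + ") else "null",
              x$n_data))
  cat(sprintf("  loglik = %.4f, deviance = %.4f, converged = %s\n",
              x$loglik, x$deviance, x$converged))
  tab <- cbind(beta = x$beta, se = x$se)
  print(round(tab, 4))
  invisible(x)
}

#' Likelihood-ratio test between nested point-process models
#'
#' The test statistic is `2 * (loglik_alt - loglik_null)`, identically the
#' deviance difference `deviance(null) - deviance(complex)`; its null
#' distribution is chi-square with degrees of freedom equal to the
#' difference in fitted parameter counts. A positive, larger statistic means
#' the element covariates improve the fit over the homogeneous null.
#'
#' @param null_fit,alt_fit Two [fit_ppm()] results on the same pattern and
#'   quadrature, with the null's covariates a subset of the alternative's.
#' @return An object of class `lrt_result`: `stat`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "ppm_fit"), inherits(alt_fit, "ppm_fit"))
  if (!all(null_fit$covariate_names %in% alt_fit$covariate_names))
    stop("models are not nested: null covariates must be a subset of the alternative's")
  if (null_fit$n_data != alt_fit$n_data ||
      abs(sum(null_fit$quad$w) - sum(alt_fit$quad$w)) > 1e-6 * sum(alt_fit$quad$w))
    stop("fits do not share a quadrature scheme")
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (stat < -1e-6)
    stop(sprintf("negative likelihood-ratio statistic (%.3g): quadrature mismatch?", stat))
  stat <- max(stat, 0)
  df <- alt_fit$rank - null_fit$rank
  if (df < 1) {
    # a model against itself: no extra parameters, no evidence
    if (stat <= 1e-6)
      return(structure(list(stat = 0, df = 0L, p_value = 1),
                       class = "lrt_result"))
    stop("alternative model has no extra parameters")
  }
  structure(list(stat = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: stat = %.4f, df = %d, p = %.4g\n", x$stat, x$df, x$p_value))
  invisible(x)
}

#' Exhaustive covariate-subset search for the best point-process model
#'
#' Fits every covariate subset of size 1..`max_covariates` (exhaustive, not
#' greedy — saturated winners exist that greedy search misses), tests each
#' against the shared null by likelihood-ratio test, and selects the best
#' model by the rule: lowest p-value, then highest deviance, then fewest
#' covariates, then alphabetical model name (a deterministic total ordering
#' of the three published criteria). `best` is `NULL` when no subset reaches
#' `p <= alpha`. Patterns with fewer than `min_cells` points are flagged
#' (`min_cells_ok = FALSE`): selection is still computed, but such sparse
#' transects are typically indistinguishable from the null.
#'
#' No multiple-testing correction is applied across the subset family; the
#' report records the number of models fitted so users can apply their own.
#'
#' @param pattern A [cell_pattern()].
#' @param elements An [element_map()] of candidate covariates.
#' @param max_covariates Largest subset size (default 5).
#' @param alpha Significance threshold (default 0.05).
#' @param min_cells Minimum reliable cell count (default 70).
#' @param channels Optional channel pre-selection (default: all).
#' @param quad Optional shared `quad_scheme`.
#' @param max_fits Abort if the subset family exceeds this size
#'   (default 1e6); pre-select channels instead.
#' @return An object of class `ppm_search`: `rows` (data frame `model`,
#'   `n_covariates`, `df`, `p_value`, `log_p`, `deviance`, `converged`,
#'   sorted by the selection rule; `log_p` keeps very strong models ordered
#'   where `p_value` underflows), `best` (character vector or `NULL`), `null_fit`,
#'   `alpha`, `n_data`, `min_cells_ok`, `n_fitted`.
#' @export
model_search <- function(pattern, elements, max_covariates = 5, alpha = 0.05,
                         min_cells = 70, channels = NULL, quad = NULL,
                         max_fits = 1e6) {
  stopifnot(inherits(pattern, "cell_pattern"), inherits(elements, "element_map"))
  if (is.null(channels)) channels <- elements$channels
  stopifnot(length(channels) >= 1)
  sizes <- seq_len(min(max_covariates, length(channels)))
  n_sub <- sum(choose(length(channels), sizes))
  if (n_sub > max_fits)
    stop(sprintf(paste0("subset family has %g models (> %g): pre-select ",
                        "channels via the 'channels' argument"), n_sub, max_fits))
  if (is.null(quad)) quad <- build_quadrature(pattern)
  des <- ppm_design(elements, quad, channels)
  const <- des$channels[des$scale == 0 | !is.finite(des$scale)]
  if (length(const)) {
    warning(sprintf("constant covariate(s) excluded from search: %s",
                    paste(const, collapse = ", ")))
    channels <- setdiff(channels, const)
  }
  Xs <- sweep(sweep(des$X[, channels, drop = FALSE], 2, des$center[channels]),
              2, des$scale[channels], `/`)
  z <- as.numeric(quad$is_data)
  null_eng <- ppm_engine(Xs[, 0, drop = FALSE], z, quad$w)
  subsets <- unlist(lapply(sizes, function(k)
    utils::combn(sort(channels), k, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(subsets, function(sub) {
    eng <- ppm_engine(Xs[, sub, drop = FALSE], z, quad$w)
    stat <- max(0, 2 * (eng$loglik - null_eng$loglik))
    df <- eng$rank - null_eng$rank
    data.frame(model = paste(sub, collapse = " + "),
               n_covariates = length(sub), df = df,
               p_value = stats::pchisq(stat, df, lower.tail = FALSE),
               # log-scale p avoids underflow ties among very strong models
               log_p = stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE),
               deviance = stat, converged = eng$converged)
  })
  rows <- do.call(rbind, rows)
  ord <- order(rows$log_p, -rows$deviance, rows$n_covariates, rows$model)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  best <- if (any(rows$p_value <= alpha))
    strsplit(rows$model[which(rows$p_value <= alpha)[1]], " \\+ ")[[1]]
  else NULL
  null_fit <- fit_ppm(pattern, NULL, quad = quad, keep_raster = FALSE)
  structure(list(rows = rows, best = best, null_fit = null_fit, alpha = alpha,
                 n_data = sum(quad$is_data), min_cells = min_cells,
                 min_cells_ok = sum(quad$is_data) >= min_cells,
                 n_fitted = nrow(rows), quad = quad),
            class = "ppm_search")
}

#' @export
print.ppm_search <- function(x, ...) {
  cat(sprintf("Model search: %d subsets fitted, n = %d cells%s\n", x$n_fitted,
              x$n_data,
              if (x$min_cells_ok) "" else sprintf(" (below min_cells = %d)", x$min_cells)))
  if (is.null(x$best)) {
    cat(sprintf("  no model reaches p <= %g: cell distribution consistent with the null\n",
                x$alpha))
  } else {
    cat("  best model:", paste(x$best, collapse = " + "), "\n")
  }
  print(utils::head(x$rows, 5))
  invisible(x)
}

#' Format a model-search result as a report table row
#'
#' One row in the flat report layout used for point-process results across
#' coupons: substrate, coupon id, best model, its p-value and deviance.
#'
#' @param search A `ppm_search` result.
#' @param coupon,substrate Identifier strings for the transect.
#' @return A one-row data frame with columns `substrate`, `coupon`, `model`,
#'   `p_value`, `deviance`.
#' @export
search_report_row <- function(search, coupon = "", substrate = "") {
  stopifnot(inherits(search, "ppm_search"))
  if (is.null(search$best)) {
    return(data.frame(substrate = substrate, coupon = coupon, model = "(null)",
                      p_value = NA_real_, deviance = NA_real_))
  }
  row <- search$rows[search$rows$model == paste(search$best, collapse = " + "), ]
  data.frame(substrate = substrate, coupon = coupon, model = row$model,
             p_value = row$p_value, deviance = row$deviance)
}
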