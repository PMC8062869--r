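# distance from each data point to the window boundary (um): exact for a
# fully valid rectangle; for masked windows, distance to the nearest
# unscanned pixel via a distance transform, combined with the rectangle edge.
boundary_distance <- function(window, x, y) {
  s <- window$pixel_size_um
  b <- pmin(x, y, window$width_px * s - x, window$height_px * s - y)
  if (!is.null(window$valid_mask)) {
    dm <- EBImage::distmap(matrix(as.numeric(window$valid_mask),
                                  nrow(window$valid_mask)))
    ij <- px_index(window, x, y)
    # distmap counts pixel steps to the nearest invalid pixel centre; the
    # boundary edge lies half a pixel closer
    b <- pmin(b, pmax(dm[ij] - 0.5, 0) * s)
  }
  b
}

default_r_grid <- function(window, n_r = 128) {
  s <- window$pixel_size_um
  rmax <- min(window$width_px, window$height_px) * s / 4
  seq(0, rmax, length.out = n_r)
}

# resolve an intensity argument (scalar, raster matrix, or ppm_fit) to a
# function giving lambda at points, plus the raster itself if available
intensity_at_points <- function(intensity, window, x, y) {
  if (inherits(intensity, "ppm_fit")) intensity <- intensity$fitted_intensity
  if (is.matrix(intensity)) {
    if (nrow(intensity) != window$height_px || ncol(intensity) != window$width_px)
      stop("intensity raster does not match the window dimensions")
    ij <- px_index(window, x, y)
    intensity[ij]
  } else {
    rep(as.numeric(intensity)[1], length(x))
  }
}

#' Inhomogeneous Ripley K-function of a cell pattern
#'
#' Estimates `K(r) = (1/|W|) sum_{i != j} 1{d_ij <= r} e_ij(r) /
#' (lambda(x_i) lambda(x_j))` for an intensity-weighted (inhomogeneous)
#' point pattern. Under the fitted model, `K(r) = pi r^2`; excess indicates
#' clustering unexplained by the intensity, deficit indicates dispersion.
#'
#' Edge corrections: `"border"` (default; reduced-sample — only points
#' farther than `r` from the window boundary contribute as reference points,
#' with the eligible mass `sum 1/lambda_i` as the normalizer) or `"none"`
#' (raw sum over all ordered pairs divided by the window area; biased low
#' near the boundary).
#'
#' @param pattern A [cell_pattern()] with `n >= 2`.
#' @param intensity Fitted intensity: a `ppm_fit`, a raster matrix over the
#'   window, or a single number (homogeneous). Must be positive at every
#'   data point.
#' @param r_grid Increasing distances in um starting at 0 (default: 128
#'   points from 0 to a quarter of the shorter window side).
#' @param correction `"border"` or `"none"`.
#' @return List of class `kfun_result` with `r_um`, `K` (NA where no
#'   reference point is eligible), `correction`.
#' @export
inhom_K <- function(pattern, intensity, r_grid = NULL,
                    correction = c("border", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "cell_pattern"))
  n <- n_points(pattern)
  if (n < 2) stop("K-function estimation needs at least 2 points")
  win <- pattern$window
  if (is.null(r_grid)) r_grid <- default_r_grid(win)
  stopifnot(r_grid[1] == 0, !is.unsorted(r_grid))
  lam <- intensity_at_points(intensity, win, pattern$x, pattern$y)
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("intensity must be positive and finite at every data point")
  invlam <- 1 / lam
  G <- length(r_grid)
  d <- as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
  # ordered pairs: (i, j) and (j, i)
  pr <- which(upper.tri(d), arr.ind = TRUE) # (i < j)
  ii <- c(pr[, 1], pr[, 2]); jj <- c(pr[, 2], pr[, 1])
  dd <- rep(d[pr], 2)
  cc <- invlam[ii] * invlam[jj]
  # bin pairs: pair counts for r >= dd, i.e. grid indices >= ks
  ks <- findInterval(dd, r_grid, left.open = TRUE) + 1L
  inside <- ks <= G
  if (correction == "none") {
    num <- numeric(G)
    if (any(inside)) {
      agg <- rowsum(cc[inside], ks[inside])
      num[as.integer(rownames(agg))] <- agg
    }
    K <- cumsum(num) / window_area(win)
  } else {
    b <- boundary_distance(win, pattern$x, pattern$y)
    kb_pt <- findInterval(b, r_grid) # eligible for grid indices <= kb
    denom_bins <- numeric(G + 1L)
    agg <- rowsum(invlam, pmin(kb_pt, G))
    denom_bins[as.integer(rownames(agg)) + 1L] <- agg
    denom <- rev(cumsum(rev(denom_bins[-1L]))) # sum over points with kb >= k
    kb <- kb_pt[ii]
    okp <- inside & ks <= kb
    M <- matrix(0, G, G)
    if (any(okp)) {
      lin <- ks[okp] + (kb[okp] - 1L) * G
      agg <- rowsum(cc[okp], lin)
      M[as.integer(rownames(agg))] <- agg
    }
    # num(k) = sum over pairs with ks <= k <= kb
    M <- apply(M, 2, cumsum)            # over ks
    M <- t(apply(M, 1, function(v) rev(cumsum(rev(v))))) # over kb
    num <- diag(M)
    K <- ifelse(denom > 0, num / denom, NA_real_)
  }
  structure(list(r_um = r_grid, K = K, correction = correction),
            class = "kfun_result")
}

#' Besag L-transform of a K-function
#'
#' `L(r) = sqrt(K(r) / pi)`, the variance-stabilized transform of Ripley's
#' reduced second moment. Under the model, `L(r) = r`.
#'
#' @param K Numeric vector of K values (all `>= 0`; NA passed through), or a
#'   `kfun_result`.
#' @return Numeric vector of L values (or a list `r_um`, `L` when given a
#'   `kfun_result`).
#' @export
L_transform <- function(K) {
  if (inherits(K, "kfun_result"))
    return(list(r_um = K$r_um, L = L_transform(K$K)))
  if (any(K < 0, na.rm = TRUE)) stop("K values must be non-negative")
  sqrt(K / pi)
}

#' Simulate an inhomogeneous Poisson point pattern
#'
#' Draws a pattern from intensity `lambda(u)` by thinning: a homogeneous
#' Poisson process at `max(lambda)` over the window's bounding box is
#' retained at each point with probability `lambda(u)/max(lambda)` (zero off
#' the valid region). The expected count is the integral of `lambda` over
#' the valid region.
#'
#' @param intensity A `ppm_fit`, raster matrix, or single number
#'   (points per um^2); all values `>= 0` and finite.
#' @param window An [obs_window()].
#' @param seed Optional integer seed (local to this call).
#' @return A [cell_pattern()]; empty when the intensity is identically zero.
#' @export
simulate_ipp <- function(intensity, window, seed = NULL) {
  stopifnot(inherits(window, "obs_window"))
  if (inherits(intensity, "ppm_fit")) intensity <- intensity$fitted_intensity
  draw <- function() {
    if (is.matrix(intensity)) {
      vals <- if (is.null(window$valid_mask)) intensity
              else intensity[window$valid_mask]
      if (any(!is.finite(vals)) || any(vals < 0))
        stop("intensity must be non-negative and finite on valid pixels")
      lam_max <- max(vals)
    } else {
      lam_max <- as.numeric(intensity)[1]
      if (!is.finite(lam_max) || lam_max < 0) stop("invalid constant intensity")
    }
    if (lam_max == 0) return(cell_pattern(numeric(0), numeric(0), window))
    s <- window$pixel_size_um
    Wum <- window$width_px * s; Hum <- window$height_px * s
    N <- stats::rpois(1, lam_max * Wum * Hum)
    if (N == 0) return(cell_pattern(numeric(0), numeric(0), window))
    x <- stats::runif(N, 0, Wum); y <- stats::runif(N, 0, Hum)
    keep <- points_inside(window, x, y)
    lam <- intensity_at_points(intensity, window, x, y)
    lam[is.na(lam)] <- 0
    keep <- keep & stats::runif(N) < lam / lam_max
    cell_pattern(x[keep], y[keep], window)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Monte-Carlo simulation envelope for the inhomogeneous L-function
#'
#' Simulates `n_sim` patterns from the fitted intensity, computes the
#' inhomogeneous L-function of the observed and each simulated pattern (all
#' evaluated under the same plug-in intensity), and returns the pointwise
#' min/max envelope. An observed curve inside the envelope gives no evidence
#' against the fitted model; with the conventional `n_sim = 99`, the
#' pointwise two-sided exceedance probability under the model is
#' `2/(n_sim + 1) = 2%`. Plug-in envelopes (intensity not re-estimated per
#' simulation) are mildly conservative.
#'
#' @param pattern Observed [cell_pattern()].
#' @param fit A `ppm_fit` (or intensity raster) whose intensity is defined
#'   on the pattern's window.
#' @param r_grid Distance grid (default as in [inhom_K()]).
#' @param n_sim Number of simulations (default 99).
#' @param seed Optional integer seed.
#' @param correction Edge correction passed to [inhom_K()].
#' @return Object of class `lfun_envelope`: `r_um`, `L_obs`, `theoretical`
#'   (= r), `envelope_lo`, `envelope_hi`, `n_sim`, `inside_envelope`,
#'   `exceed_fraction`, `exit_ranges` (data frame of r intervals where the
#'   observed curve leaves the envelope).
#' @export
envelope_L <- function(pattern, fit, r_grid = NULL, n_sim = 99, seed = NULL,
                       correction = "border") {
  stopifnot(inherits(pattern, "cell_pattern"))
  if (n_sim < 1) stop("n_sim must be >= 1")
  win <- pattern$window
  if (is.null(r_grid)) r_grid <- default_r_grid(win)
  intensity <- if (inherits(fit, "ppm_fit")) fit$fitted_intensity else fit
  L_obs <- L_transform(inhom_K(pattern, intensity, r_grid, correction))$L
  run <- function() {
    sims <- matrix(NA_real_, n_sim, length(r_grid))
    for (k in seq_len(n_sim)) {
      pat <- simulate_ipp(intensity, win)
      tries <- 0
      while (n_points(pat) < 2 && tries < 50) {
        pat <- simulate_ipp(intensity, win); tries <- tries + 1
      }
      if (n_points(pat) < 2)
        stop("fitted intensity too low to simulate patterns with >= 2 points")
      sims[k, ] <- L_transform(inhom_K(pat, intensity, r_grid, correction))$L
    }
    sims
  }
  sims <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  lo <- apply(sims, 2, function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  hi <- apply(sims, 2, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  usable <- !is.na(L_obs) & !is.na(lo) & !is.na(hi)
  outside <- usable & (L_obs < lo | L_obs > hi)
  exit_ranges <- data.frame(r_from = numeric(0), r_to = numeric(0))
  if (any(outside)) {
    rl <- rle(outside)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    sel <- which(rl$values)
    exit_ranges <- data.frame(r_from = r_grid[starts[sel]],
                              r_to = r_grid[ends[sel]])
  }
  structure(list(r_um = r_grid, L_obs = L_obs, theoretical = r_grid,
                 envelope_lo = lo, envelope_hi = hi, n_sim = n_sim,
                 inside_envelope = !any(outside),
                 exceed_fraction = if (any(usable)) mean(outside[usable]) else NA_real_,
                 exit_ranges = exit_ranges),
            class = "lfun_envelope")
}

#' @export
print.lfun_envelope <- function(x, ...) {
  cat(sprintf("L-function envelope (%d simulations): observed curve %s\n",
              x$n_sim,
              if (x$inside_envelope) "inside the envelope at all r"
              else sprintf("outside over %d range(s) (%.1f%% of r values)",
                           nrow(x$exit_ranges), 100 * x$exceed_fraction)))
  invisible(x)
}

#' @export
plot.lfun_envelope <- function(x, ...) {
  ok <- !is.na(x$envelope_lo)
  graphics::plot(x$r_um, x$theoretical, type = "n",
                 xlab = "r (um)", ylab = "L(r)",
                 ylim = range(c(x$L_obs, x$envelope_lo, x$envelope_hi), na.rm = TRUE), ...)
  graphics::polygon(c(x$r_um[ok], rev(x$r_um[ok])),
                    c(x$envelope_lo[ok], rev(x$envelope_hi[ok])),
                    col = "grey85", border = NA)
  graphics::lines(x$r_um, x$theoretical, lty = 2)
  graphics::lines(x$r_um, x$L_obs, col = "red3", lwd = 1.5)
  invisible(x)
}
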