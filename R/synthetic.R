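#' Synthetic grain scene description
#'
#' Parameters of a synthetic SEM/XEDS transect: an elliptical mineral grain
#' (e.g. Fe/S-rich pyrite or Fe/Ti-rich ilmenite) embedded in a Si/Al/O
#' silicate matrix. The default window is a 500 x 768 px portion of a
#' transect at 0.05 um/px; `full_scale = TRUE` gives the full 1024 x 1536 px
#' acquisition-tile geometry. Element signals are arbitrary detector-like
#' counts; point-process fits standardize covariates, so units drop out.
#'
#' @param width_px,height_px,pixel_size_um Window geometry.
#' @param grain Ellipse parameters in micrometres: list with `cx`, `cy`
#'   (centre), `rx`, `ry` (semi-axes), `theta` (rotation, radians). The
#'   default is placed at the window centre; the grain must lie strictly
#'   inside the window.
#' @param matrix_composition,grain_composition Named vectors of mean signal
#'   per element outside/inside the grain. Elements present in only one are
#'   taken as 0 in the other.
#' @param noise_sd Per-element Gaussian noise standard deviation (single
#'   value recycled, or named vector). The default 1 keeps minor-element
#'   channels at a physical signal-to-noise ratio: detector counting noise
#'   cannot routinely drive signals far below zero, so after truncation at 0
#'   the channels remain approximately count-like.
#' @param psf_sigma_px Gaussian point-spread blur (sd, pixels) applied to
#'   the deterministic grain/matrix structure. The default 8 px (0.4 um at
#'   the default pixel size) mimics the X-ray generation volume at typical
#'   SEM voltages, which is far wider than one high-magnification pixel, so
#'   real element maps never show single-pixel composition steps. Set 0 for
#'   an idealized hard-edged grain.
#' @param noise_smooth_px Gaussian smoothing (sd, pixels) of the noise
#'   field, rescaled to keep the nominal marginal sd; the default 8 px
#'   matches the PSF scale. 0 gives pixel-independent noise.
#' @param seed Integer seed stored with the scene; all generators are pure
#'   functions of (scene, seed).
#' @param full_scale If `TRUE`, use the 1024 x 1536 px full-tile preset.
#' @return An object of class `grain_scene`.
#' @export
grain_scene <- function(width_px = 500, height_px = 768, pixel_size_um = 0.05,
                        grain = NULL,
                        matrix_composition = c(Si = 25, Al = 8, O = 45,
                                               Fe = 2, S = 1, Ti = 1),
                        grain_composition = c(Si = 8, Al = 3, O = 35,
                                              Fe = 30, S = 15, Ti = 1),
                        noise_sd = 1, psf_sigma_px = 8, noise_smooth_px = 8,
                        seed = 1L, full_scale = FALSE) {
  if (full_scale) { width_px <- 1024; height_px <- 1536 }
  Wum <- width_px * pixel_size_um
  Hum <- height_px * pixel_size_um
  if (is.null(grain))
    grain <- list(cx = Wum / 2, cy = Hum / 2,
                  rx = 0.2 * Wum, ry = 0.18 * Hum, theta = 0.4)
  stopifnot(grain$rx > 0, grain$ry > 0)
  rmax <- max(grain$rx, grain$ry)
  if (grain$cx - rmax < 0 || grain$cx + rmax > Wum ||
      grain$cy - rmax < 0 || grain$cy + rmax > Hum)
    stop("grain must lie strictly inside the window")
  els <- union(names(matrix_composition), names(grain_composition))
  mc <- stats::setNames(numeric(length(els)), els)
  gc <- mc
  mc[names(matrix_composition)] <- matrix_composition
  gc[names(grain_composition)] <- grain_composition
  if (any(mc < 0) || any(gc < 0)) stop("compositions must be non-negative")
  if (length(noise_sd) == 1) noise_sd <- stats::setNames(rep(noise_sd, length(els)), els)
  stopifnot(all(els %in% names(noise_sd)))
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_um = pixel_size_um, grain = grain,
                 matrix_composition = mc, grain_composition = gc,
                 noise_sd = noise_sd[els], psf_sigma_px = psf_sigma_px,
                 noise_smooth_px = noise_smooth_px, seed = as.integer(seed)),
            class = "grain_scene")
}

#' Grain membership mask of a scene
#'
#' @param scene A [grain_scene()].
#' @return Logical matrix, `TRUE` inside the grain ellipse.
#' @export
grain_mask <- function(scene) {
  stopifnot(inherits(scene, "grain_scene"))
  s <- scene$pixel_size_um
  cx <- (seq_len(scene$width_px) - 0.5) * s
  cy <- (seq_len(scene$height_px) - 0.5) * s
  g <- scene$grain
  dx <- outer(cy - g$cy, cx - g$cx, function(a, b) b) # constant over rows
  dy <- outer(cy - g$cy, cx - g$cx, function(a, b) a)
  u <- dx * cos(g$theta) + dy * sin(g$theta)
  v <- -dx * sin(g$theta) + dy * cos(g$theta)
  (u / g$rx)^2 + (v / g$ry)^2 <= 1
}

#' Generate a synthetic element map from a grain scene
#'
#' Each channel is the matrix mean, overwritten by the grain mean inside the
#' grain ellipse, convolved with the scene's point-spread blur, plus seeded
#' Gaussian noise truncated at 0. Identical (scene, seed) give bit-identical
#' maps.
#'
#' @param scene A [grain_scene()].
#' @param seed Optional seed overriding the scene's.
#' @return An [element_map()].
#' @export
make_element_map <- function(scene, seed = NULL) {
  stopifnot(inherits(scene, "grain_scene"))
  seed <- seed %||% scene$seed
  win <- obs_window(scene$width_px, scene$height_px, scene$pixel_size_um)
  inside <- grain_mask(scene)
  els <- names(scene$matrix_composition)
  vals <- withr::with_seed(seed, {
    lapply(stats::setNames(els, els), function(k) {
      base <- matrix(scene$matrix_composition[k], win$height_px, win$width_px)
      base[inside] <- scene$grain_composition[k]
      if (scene$psf_sigma_px > 0) base <- gaussian_blur(base, scene$psf_sigma_px)
      if (scene$noise_sd[k] > 0) {
        noise <- matrix(stats::rnorm(length(base), 0, scene$noise_sd[k]),
                        win$height_px, win$width_px)
        if (scene$noise_smooth_px > 0) {
          noise <- gaussian_blur(noise, scene$noise_smooth_px)
          # restore the nominal marginal sd lost to smoothing
          noise <- noise * scene$noise_sd[k] / stats::sd(noise)
        }
        base <- base + noise
      }
      pmax(base, 0)
    })
  })
  element_map(win, vals, provenance = sprintf("synthetic grain scene, seed %d", seed))
}

#' Planted mineral-selectivity ground truth
#'
#' The log-linear intensity a synthetic cell pattern is drawn from:
#' `lambda(u) = exp(beta0 + sum_k beta_k z_k(u))`, with `z_k` the z-scored
#' element channels (zero mean, unit variance over valid pixels) — the same
#' covariate scale on which [fit_ppm()] reports coefficients, so planted and
#' estimated coefficients are directly comparable.
#'
#' @param beta0 Intercept (log points per um^2 at average composition).
#' @param beta Named vector of selectivity coefficients per element.
#' @param expected_n Expected point count (filled in by
#'   [simulate_selective_cells()]).
#' @return Object of class `selectivity_truth`.
#' @export
selectivity_truth <- function(beta0, beta, expected_n = NA_real_) {
  stopifnot(is.numeric(beta0), length(beta0) == 1, !is.null(names(beta)))
  structure(list(beta0 = beta0, beta = beta, expected_n = expected_n),
            class = "selectivity_truth")
}

# z-scored channel rasters over valid pixels
standardized_channels <- function(map, channels) {
  win <- map$window
  lapply(stats::setNames(channels, channels), function(k) {
    v <- map$values[[k]]
    px <- if (is.null(win$valid_mask)) as.vector(v) else v[win$valid_mask]
    (v - mean(px)) / stats::sd(px)
  })
}

#' Simulate cells selectively colonizing mineral surfaces
#'
#' Draws an inhomogeneous Poisson pattern from
#' `lambda(u) = exp(beta0 + sum_k beta_k z_k(u))` over the element map's
#' z-scored channels, by thinning ([simulate_ipp()]). Either give `beta0`
#' directly or a `target_n`: then `beta0` is calibrated so the expected
#' count equals `target_n` (the observed range in comparable transects is
#' roughly 70-1,500 cells).
#'
#' @param map An [element_map()].
#' @param beta Named coefficient vector over (a subset of) the map's
#'   channels; zero coefficients give a homogeneous pattern.
#' @param beta0 Intercept, or `NULL` to calibrate from `target_n`.
#' @param target_n Expected cell count used when `beta0` is `NULL`.
#' @param seed Optional integer seed.
#' @return A [cell_pattern()] with attribute `"truth"`, a
#'   [selectivity_truth()] recording `beta0`, `beta` and the realized
#'   `expected_n` (the intensity integral; errors above 1e6).
#' @export
simulate_selective_cells <- function(map, beta, beta0 = NULL, target_n = NULL,
                                     seed = NULL) {
  stopifnot(inherits(map, "element_map"))
  if (!all(names(beta) %in% map$channels))
    stop("beta names must be channels of the element map")
  win <- map$window
  s <- win$pixel_size_um
  zs <- standardized_channels(map, names(beta))
  eta <- matrix(0, win$height_px, win$width_px)
  for (k in names(beta)) eta <- eta + beta[k] * zs[[k]]
  valid <- win$valid_mask %||% matrix(TRUE, win$height_px, win$width_px)
  if (is.null(beta0)) {
    if (is.null(target_n)) stop("give either beta0 or target_n")
    beta0 <- log(target_n / (sum(exp(eta[valid])) * s^2))
  }
  lam <- exp(beta0 + eta)
  expected_n <- sum(lam[valid]) * s^2
  if (expected_n > 1e6)
    stop(sprintf("runaway intensity: expected count %.3g > 1e6", expected_n))
  lam[!valid] <- NA_real_
  pat <- simulate_ipp(lam, win, seed = seed)
  attr(pat, "truth") <- selectivity_truth(beta0, beta, expected_n)
  attr(pat, "lambda") <- lam
  pat
}

# pixel offsets of a stamp shape (relative to its centre), random orientation
stamp_shape <- function(kind, area_px, rng_theta) {
  if (kind == "cocci") {
    r <- sqrt(area_px / pi)
    R <- ceiling(r)
    g <- expand.grid(di = -R:R, dj = -R:R)
    g[g$di^2 + g$dj^2 <= r^2, , drop = FALSE]
  } else if (kind == "rod") {
    # 4:1 ellipse
    b <- sqrt(area_px / (4 * pi)); a <- 4 * b
    R <- ceiling(a)
    g <- expand.grid(di = -R:R, dj = -R:R)
    u <- g$dj * cos(rng_theta) + g$di * sin(rng_theta)
    v <- -g$dj * sin(rng_theta) + g$di * cos(rng_theta)
    g[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
  } else if (kind == "filament") {
    # thin straight filament, ~50:1
    w <- max(1, sqrt(area_px / 50))
    L <- area_px / w
    R <- ceiling(L / 2 + 1)
    g <- expand.grid(di = -R:R, dj = -R:R)
    u <- g$dj * cos(rng_theta) + g$di * sin(rng_theta)
    v <- -g$dj * sin(rng_theta) + g$di * cos(rng_theta)
    g[abs(u) <= L / 2 & abs(v) <= w / 2, , drop = FALSE]
  } else { # fungal: bifurcating thin filament with spore-like disk tips
    w <- max(1, sqrt(area_px / 60))
    L <- 0.6 * area_px / w
    R <- ceiling(L + 3)
    g <- expand.grid(di = -R:R, dj = -R:R)
    rot <- function(th) {
      u <- g$dj * cos(th) + g$di * sin(th)
      v <- -g$dj * sin(th) + g$di * cos(th)
      list(u = u, v = v)
    }
    a1 <- rot(rng_theta); a2 <- rot(rng_theta + 0.7)
    stem <- a1$u >= 0 & a1$u <= L & abs(a1$v) <= w / 2
    branch <- a2$u >= 0 & a2$u <= 0.7 * L & abs(a2$v) <= w / 2
    tip1 <- (g$dj - L * cos(rng_theta))^2 + (g$di - L * sin(rng_theta))^2 <= (1.5 * w)^2
    tip2 <- (g$dj - 0.7 * L * cos(rng_theta + 0.7))^2 +
      (g$di - 0.7 * L * sin(rng_theta + 0.7))^2 <= (1.5 * w)^2
    g[stem | branch | tip1 | tip2, , drop = FALSE]
  }
}

#' Stamp a feature mask around a cell pattern
#'
#' Places one feature per point: a disk (cocci), a 4:1 ellipse (rod), or a
#' thin elongated shape (filament) for cells, and bifurcating filaments with
#' spore-like tips for fungal features. Morphologies are drawn from
#' `morphology_mix`; feature areas are log-normal around `mean_area_um2`.
#' Overlapping stamps are relocated to a fresh uniform position (up to 100
#' tries, then stamped with a warning); set `merge_overlaps = TRUE` to allow
#' overlaps (later features overwrite).
#'
#' @param pattern A [cell_pattern()] of cell positions.
#' @param morphology_mix Named fractions over
#'   `c("cocci", "rod", "filament")`, summing to 1.
#' @param mean_area_um2 Mean feature area (default 0.1, the dominant cell
#'   size on comparable rock surfaces).
#' @param area_sdlog Log-normal sd of feature areas (default 0.25).
#' @param n_fungal Number of additional fungal features stamped at uniform
#'   positions (default 0).
#' @param merge_overlaps Allow overlapping stamps (default `FALSE`).
#' @param seed Optional integer seed.
#' @return A [feature_mask()] with attribute `"truth_class"`: the generated
#'   morphology per feature id.
#' @export
make_feature_mask <- function(pattern, morphology_mix = c(cocci = 0.3, rod = 0.6,
                                                          filament = 0.1),
                              mean_area_um2 = 0.1, area_sdlog = 0.25,
                              n_fungal = 0, merge_overlaps = FALSE,
                              seed = NULL) {
  stopifnot(inherits(pattern, "cell_pattern"))
  if (abs(sum(morphology_mix) - 1) > 1e-8)
    stop("morphology_mix fractions must sum to 1")
  win <- pattern$window
  s <- win$pixel_size_um
  H <- win$height_px; W <- win$width_px
  build <- function() {
    labels <- matrix(0L, H, W)
    n <- n_points(pattern)
    total <- n + n_fungal
    if (total == 0)
      return(list(labels = labels, classes = character(0), truth = character(0)))
    kinds <- c(
      if (n > 0) sample(names(morphology_mix), n, replace = TRUE,
                        prob = morphology_mix) else character(0),
      rep("fungal", n_fungal))
    xs <- c(pattern$x, stats::runif(n_fungal, 0, W * s))
    ys <- c(pattern$y, stats::runif(n_fungal, 0, H * s))
    classes <- ifelse(kinds == "fungal", "fungal", "cell")
    truth <- character(total)
    for (f in seq_len(total)) {
      area_um <- stats::rlnorm(1, log(mean_area_um2 *
                                        if (kinds[f] == "fungal") 6 else 1),
                               area_sdlog)
      area_px <- max(2, round(area_um / s^2))
      off <- stamp_shape(kinds[f], area_px, stats::runif(1, 0, pi))
      cx <- xs[f]; cy <- ys[f]
      placed <- FALSE
      for (try in seq_len(101)) {
        ij <- px_index(win, cx, cy)
        ii <- ij[1] + off$di; jj <- ij[2] + off$dj
        ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
        if (all(ok)) {
          lin <- cbind(ii, jj)
          free <- merge_overlaps || all(labels[lin] == 0L)
          if (free || try > 100) {
            if (!free) warning("could not avoid overlap after 100 relocations")
            labels[lin] <- f
            placed <- TRUE
            break
          }
        }
        cx <- stats::runif(1, 0, W * s); cy <- stats::runif(1, 0, H * s)
      }
      if (!placed) warning(sprintf("feature %d could not be placed", f))
      truth[f] <- kinds[f]
    }
    list(labels = labels, classes = classes, truth = truth)
  }
  res <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  mask <- feature_mask(res$labels,
                       stats::setNames(res$classes,
                                       as.character(seq_along(res$classes))),
                       win)
  attr(mask, "truth_class") <- res$truth
  mask
}

#' Synthetic community table with planted taxa-chemistry correlations
#'
#' Dirichlet-distributed compositions in which selected taxa's concentration
#' parameters scale with a bulk-chemistry element of each sample's
#' substrate, planting positive taxon-element correlations while all other
#' taxa stay uncorrelated.
#'
#' @param n_samples,n_taxa Table dimensions (defaults 16 and 24).
#' @param chem A [bulk_chem_table()]; samples cycle through its substrates.
#' @param linked_taxa Named list: taxon name -> `list(element =, effect =)`.
#'   Effect ~2 yields strong (> 0.6) planted correlations at n = 16.
#' @param base_concentration Dirichlet concentration of unlinked taxa
#'   (default 5).
#' @param groups Optional per-sample group labels.
#' @param seed Optional integer seed.
#' @return A [community_table()] with `substrates` set.
#' @export
make_community_fixture <- function(n_samples = 16, n_taxa = 24, chem,
                                   linked_taxa = list(),
                                   base_concentration = 5, groups = NULL,
                                   seed = NULL) {
  chem <- as.matrix(chem)
  subs <- rep(rownames(chem), length.out = n_samples)
  taxa <- paste0("taxon", seq_len(n_taxa))
  # ensure linked taxa are present by name
  if (length(linked_taxa)) {
    extra <- setdiff(names(linked_taxa), taxa)
    if (length(extra)) taxa[seq_along(extra)] <- extra
    for (nm in names(linked_taxa))
      if (!linked_taxa[[nm]]$element %in% colnames(chem))
        stop("linked elements must be columns of the chemistry table")
  }
  draw <- function() {
    ab <- matrix(0, n_samples, n_taxa, dimnames = list(
      paste0("sample", seq_len(n_samples)), taxa))
    for (i in seq_len(n_samples)) {
      alpha <- rep(base_concentration, n_taxa)
      for (nm in names(linked_taxa)) {
        el <- linked_taxa[[nm]]$element
        zv <- (chem[subs[i], el] - mean(chem[, el])) /
          (stats::sd(chem[, el]) + 1e-12)
        alpha[match(nm, taxa)] <-
          max(0.1, base_concentration * (1 + linked_taxa[[nm]]$effect * zv))
      }
      g <- stats::rgamma(n_taxa, shape = alpha)
      ab[i, ] <- g / sum(g)
    }
    ab
  }
  ab <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  community_table(ab, groups = groups, substrates = subs)
}
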