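# Independent brute-force oracles and small fixture builders shared by the
# suite. These deliberately re-derive quantities from first principles
# (double loops, direct kernel sums) so they cannot share code paths with
# the implementation they check.

# direct double-loop inhomogeneous K estimator
bf_inhom_K <- function(pattern, lambda, r_grid, correction = "border") {
  n <- n_points(pattern)
  win <- pattern$window
  s <- win$pixel_size_um
  lam <- if (length(lambda) == 1) rep(lambda, n) else lambda
  b <- pmin(pattern$x, pattern$y,
            win$width_px * s - pattern$x, win$height_px * s - pattern$y)
  sapply(r_grid, function(r) {
    num <- 0; den <- 0
    for (i in seq_len(n)) {
      if (correction == "border" && b[i] < r) next
      den <- den + 1 / lam[i]
      for (j in seq_len(n)) {
        if (j == i) next
        d <- sqrt((pattern$x[i] - pattern$x[j])^2 +
                  (pattern$y[i] - pattern$y[j])^2)
        if (d <= r) num <- num + 1 / (lam[i] * lam[j])
      }
    }
    if (correction == "none") num / window_area(win)
    else if (den > 0) num / den else NA_real_
  })
}

# direct per-pair SIMPER decomposition
bf_simper <- function(ab, groups, g1, g2) {
  ia <- which(groups == g1); ib <- which(groups == g2)
  contrib <- rep(0, ncol(ab))
  np <- 0
  for (a in ia) for (b in ib) {
    np <- np + 1
    tot <- sum(ab[a, ] + ab[b, ])
    contrib <- contrib + abs(ab[a, ] - ab[b, ]) / tot
  }
  stats::setNames(contrib / np, colnames(ab))
}

# direct Gaussian product-kernel sum with the h/4 bandwidth convention
bf_kernel_density <- function(pattern, h, gx, gy) {
  n <- n_points(pattern)
  sx <- h[1] / 4; sy <- h[2] / 4
  z <- matrix(0, length(gx), length(gy))
  for (k in seq_len(n)) {
    z <- z + outer(stats::dnorm(gx, pattern$x[k], sx),
                   stats::dnorm(gy, pattern$y[k], sy))
  }
  z / n
}

# digitized disk as a single-feature mask, centred in a padded window
disk_feature_mask <- function(r_px, pixel_size_um = 1, offset = c(0, 0)) {
  R <- r_px + 3
  n <- 2 * R + 1
  ctr <- R + 1
  ij <- expand.grid(i = seq_len(n), j = seq_len(n))
  inside <- (ij$i - ctr - offset[2])^2 + (ij$j - ctr - offset[1])^2 <= r_px^2
  lab <- matrix(0L, n, n)
  lab[cbind(ij$i[inside], ij$j[inside])] <- 1L
  feature_mask(lab, c("1" = "cell"), obs_window(n, n, pixel_size_um))
}

# small random community table with rows summing to 1
random_community <- function(n_samples, n_taxa, seed, groups = NULL) {
  withr::with_seed(seed, {
    ab <- matrix(stats::rgamma(n_samples * n_taxa, shape = 1), n_samples)
    ab <- ab / rowSums(ab)
    colnames(ab) <- paste0("t", seq_len(n_taxa))
    community_table(ab, groups = groups)
  })
}

# a grain scene whose only spatially structured channel is S (the others are
# flat + noise), used for planted-covariate recovery
selection_scene <- function(seed, width_px = 250, height_px = 384) {
  grain_scene(width_px = width_px, height_px = height_px, seed = seed,
              matrix_composition = c(Si = 25, Al = 8, Fe = 5, S = 1, Ti = 1),
              grain_composition = c(Si = 25, Al = 8, Fe = 5, S = 15, Ti = 1))
}
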