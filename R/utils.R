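`%||%` <- function(a, b) if (is.null(a)) b else a

# index-clamped matrix shift (edge replication), used by the blur
shift_clamp <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  m[pmin(pmax(seq_len(H) - di, 1L), H), pmin(pmax(seq_len(W) - dj, 1L), W),
    drop = FALSE]
}

#' Separable Gaussian blur of a raster
#'
#' Truncated-Gaussian separable convolution (radius 3 sigma) with edge
#' replication; used for optional covariate pre-smoothing and for building
#' spatially structured noise fields.
#'
#' @param m Numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels.
#' @return Blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  R <- max(1L, ceiling(3 * sigma_px))
  w <- stats::dnorm(-R:R, sd = sigma_px)
  w <- w / sum(w)
  out <- matrix(0, nrow(m), ncol(m))
  for (k in -R:R) out <- out + w[k + R + 1] * shift_clamp(m, 0, k)
  m2 <- out
  out <- matrix(0, nrow(m), ncol(m))
  for (k in -R:R) out <- out + w[k + R + 1] * shift_clamp(m2, k, 0)
  out
}

#' Gaussian pre-smoothing of every channel of an element map
#'
#' @param map An [element_map()].
#' @param sigma_px Standard deviation in pixels.
#' @return A smoothed [element_map()].
#' @export
smooth_element_map <- function(map, sigma_px) {
  stopifnot(inherits(map, "element_map"))
  vals <- lapply(map$values, gaussian_blur, sigma_px = sigma_px)
  element_map(map$window, vals,
              provenance = paste0(map$provenance,
                                  sprintf(" [smoothed sigma=%g px]", sigma_px)))
}
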