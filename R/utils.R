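`%||%` <- function(a, b) if (is.null(a)) b else a

#' Otsu threshold of a numeric sample
#'
#' Maximizes between-class variance on a binned histogram of `x` and returns
#' the cut value (midpoint between the two classes). Used as the default
#' automatic threshold for vessel segmentation, body segmentation and CD3
#' gating when no explicit value is supplied.
#'
#' @param x numeric vector (NAs dropped).
#' @param n_bins number of histogram bins.
#' @return threshold value, or `NA` if `x` is degenerate (all equal).
#' @export
otsu_threshold <- function(x, n_bins = 256) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  rng <- range(x)
  if (diff(rng) == 0) return(NA_real_)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[ok] <- (mu_t * w0[ok] - mu[ok])^2 / (w0[ok] * w1[ok])
  # the maximizer is a plateau when the valley between modes is empty;
  # take its midpoint for a centered cut
  ks <- which(sigma_b >= max(sigma_b) - 1e-12)
  breaks[round(mean(range(ks))) + 1]
}

# Mode of a sample estimated as the midpoint of the fullest histogram bin.
hist_mode <- function(x, n_bins = 64) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  k <- which.max(h)
  (breaks[k] + breaks[k + 1]) / 2
}

# Normalized 1D Gaussian kernel sampled at integer offsets, truncated at
# `truncate` sigmas. sigma in voxel units; sigma <= 0 gives the identity.
gaussian_kernel1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable Gaussian blur of a 3D array; sigma_vox per axis (voxel units),
# zero padding at the boundary (mass near the edge is lost, by design).
gaussian_blur3 <- function(arr, sigma_vox, truncate = 4) {
  sigma_vox <- rep_len(sigma_vox, 3)
  if (all(sigma_vox <= 0)) return(arr)
  kernels <- lapply(sigma_vox, gaussian_kernel1d, truncate = truncate)
  cpp_sepconv3(as.numeric(arr), dim(arr), kernels)
}

# Ellipsoid indicator on a voxel grid: voxel centers (i - 0.5) * spacing
# with ((p - center) / radii)^2 summing to <= 1.
ellipsoid_mask <- function(grid_shape, spacing, center, radii) {
  ax <- lapply(1:3, function(a) {
    ((seq_len(grid_shape[a]) - 0.5) * spacing[a] - center[a]) / radii[a]
  })
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  q <= 1
}

# Uniform direction on the unit sphere.
runif_sphere <- function(n = 1) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}
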