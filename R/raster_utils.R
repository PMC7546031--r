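# Shared array machinery: separable Gaussian blur, linear resampling, integer
# shifts, ball structuring elements, Otsu threshold. All arrays are (z, y, x).

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Apply an n_new x n_old linear operator along one axis of a 3D array.
apply_axis <- function(a, M, axis) {
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  b <- aperm(a, perm)
  d <- dim(b)
  out <- M %*% matrix(b, nrow = d[1])
  dim(out) <- c(nrow(M), d[2], d[3])
  aperm(out, order(perm))
}

# Truncated-and-renormalized Gaussian convolution matrix (edge-corrected).
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (j in -r:r) {
    i <- seq_len(n)
    ok <- i + j >= 1L & i + j <= n
    M[cbind(i[ok], i[ok] + j)] <- kernel[j + r + 1L]
  }
  M / rowSums(M)
}

#' Separable Gaussian blur of a 3D volume
#' @param a 3D numeric array `(z, y, x)`.
#' @param sigma_vox standard deviation in voxels per axis `(z, y, x)`;
#'   entries `<= 0` skip that axis.
#' @return blurred array of the same shape.
#' @keywords internal
blur3d <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (!is.finite(s) || s <= 1e-8) next
    a <- apply_axis(a, conv_matrix(dim(a)[ax], gauss_kernel(s)), ax)
  }
  a
}

# Linear interpolation matrix resampling an axis from spacing `old` to `new`;
# voxel centres at (i - 0.5) * spacing, edges clamped.
resample_matrix <- function(n_old, old, new) {
  n_new <- max(2L, as.integer(round(n_old * old / new)))
  g <- ((seq_len(n_new) - 0.5) * new) / old + 0.5 # fractional index in old grid
  i0 <- pmin(pmax(floor(g), 1), n_old)
  i1 <- pmin(i0 + 1, n_old)
  w <- pmin(pmax(g - i0, 0), 1)
  M <- matrix(0, n_new, n_old)
  M[cbind(seq_len(n_new), i0)] <- M[cbind(seq_len(n_new), i0)] + (1 - w)
  M[cbind(seq_len(n_new), i1)] <- M[cbind(seq_len(n_new), i1)] + w
  M
}

# Trilinear resampling of a 3D array to isotropic spacing.
resample_isotropic <- function(a, voxel_spacing, target = min(voxel_spacing)) {
  for (ax in 1:3) {
    if (abs(voxel_spacing[ax] - target) < 1e-12) next
    a <- apply_axis(a, resample_matrix(dim(a)[ax], voxel_spacing[ax], target), ax)
  }
  list(data = a, spacing = target)
}

# Integer-voxel translation with zero fill; shift = (dz, dy, dx) is the
# displacement applied to the content.
shift_array3d <- function(a, shift, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    s <- as.integer(shift[ax])
    if (abs(s) >= d[ax]) return(out)
    if (s >= 0) { src[[ax]] <- 1:(d[ax] - s); dst[[ax]] <- (1 + s):d[ax] }
    else { src[[ax]] <- (1 - s):d[ax]; dst[[ax]] <- 1:(d[ax] + s) }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Integer offsets within a physical-unit ball of `radius_um`, given the voxel
# spacing: the anisotropy-aware structuring element.
ball_offsets_um <- function(radius_um, spacing) {
  if (radius_um <= 0) return(matrix(0L, 1, 3))
  r <- pmax(0L, as.integer(floor(radius_um / spacing)))
  g <- as.matrix(expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3]))
  keep <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2 <= radius_um^2 + 1e-9
  g[keep, , drop = FALSE]
}

# Integer offsets within a Euclidean ball of `radius` voxels.
ball_offsets <- function(radius) {
  if (radius <= 0) return(matrix(0L, 1, 3))
  r <- as.integer(floor(radius))
  g <- as.matrix(expand.grid(dz = -r:r, dy = -r:r, dx = -r:r))
  g[g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= radius^2 + 1e-9, , drop = FALSE]
}

binary_dilate <- function(mask, offsets) {
  out <- array(FALSE, dim(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- out | shift_array3d(mask, offsets[i, ], fill = FALSE)
  }
  out
}

binary_erode <- function(mask, offsets) {
  out <- array(TRUE, dim(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- out & shift_array3d(mask, offsets[i, ], fill = FALSE)
  }
  out
}

#' Otsu threshold of an intensity volume
#'
#' Maximizes between-class variance over a 256-bin histogram; the standard
#' automatic global threshold for bimodal fluorescence intensity.
#'
#' @param v numeric vector or array of intensities.
#' @param n_bins histogram resolution.
#' @return threshold on the intensity scale of `v`.
#' @export
otsu_threshold <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- w0 * (1 - w0)
  sb <- (mu_t * w0 - mu)^2 / ifelse(denom > 0, denom, NA)
  k <- which.max(sb)
  mids[k]
}

# Connected-component labelling of a logical 3D array (26- or 6-connectivity).
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- .cc_label_3d(as.logical(mask), as.integer(d), as.integer(connectivity))
  array(lab, d)
}
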