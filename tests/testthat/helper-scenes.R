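# Fixture builders shared across the suite. Everything is generated in code;
# the default anisotropic spacing (1.0, 0.3, 0.3) um mirrors the pipeline's
# study conditions.

SP_DEFAULT <- c(1.0, 0.3, 0.3)

# digitized solid ellipsoid mask on an anisotropic grid, centre in the middle
digitize_ellipsoid <- function(semi_axes, spacing = SP_DEFAULT, pad = 3) {
  ext <- semi_axes + pad
  dims <- ceiling(2 * ext / spacing)
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
  ctr <- ext
  q <- outer(outer((ax[[1]] - ctr[1])^2 / semi_axes[1]^2,
                   (ax[[2]] - ctr[2])^2 / semi_axes[2]^2, "+"),
             (ax[[3]] - ctr[3])^2 / semi_axes[3]^2, "+")
  array(q <= 1, dims)
}

digitize_sphere <- function(r, spacing = SP_DEFAULT, pad = 3) {
  digitize_ellipsoid(c(r, r, r), spacing, pad)
}

sphere_mask <- function(r, spacing = SP_DEFAULT) {
  cell_mask(digitize_sphere(r, spacing), spacing)
}

# one-cell noiseless scene: a sphere of radius r at the grid centre
sphere_scene <- function(r = 5, spacing = SP_DEFAULT, pad = 6, seed = 7,
                         noise = noise_spec(0, 0, 0), psf = c(0, 0, 0),
                         n_frames = 1, drift = c(0, 0, 0)) {
  dims <- pmax(ceiling(2 * (r + pad) / spacing), 8)
  drift_tot <- abs(drift) * (n_frames - 1)
  dims <- pmax(dims, ceiling((2 * (r + pad) + 2 * drift_tot) / spacing))
  ctr <- dims * spacing / 2 - drift_tot / 2
  scene_spec(grid_shape = dims, voxel_spacing = spacing,
             cells = list(cell_spec(center = ctr, semi_axes = rep(r, 3))),
             drift = drift, noise = noise, psf_sigma = psf,
             n_frames = n_frames, seed = seed)
}

# random blob-ish small masks for oracle-equivalence checks
random_blob_mask <- function(seed, spacing = SP_DEFAULT) {
  withr::with_seed(seed, {
    dims <- c(10L, 24L, 24L)
    m <- array(FALSE, dims)
    n_blob <- sample(2:4, 1)
    ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
    for (b in seq_len(n_blob)) {
      ctr <- c(stats::runif(1, 3, 7), stats::runif(2, 2.5, 4.5))
      r <- stats::runif(1, 1.2, 2.4)
      q <- outer(outer((ax[[1]] - ctr[1])^2, (ax[[2]] - ctr[2])^2, "+"),
                 (ax[[3]] - ctr[3])^2, "+")
      m <- m | (q <= r^2)
    }
    m
  })
}
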