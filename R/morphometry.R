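#' Mesh the surface of a binary mask in physical coordinates
#'
#' The mask is Gaussian-smoothed (physical sigma), resampled to an isotropic
#' grid at the finest axis spacing, and triangulated by marching tetrahedra at
#' a volume-matched iso level: the level is chosen so the super-threshold
#' volume of the smoothed field equals the voxel-count volume of the mask,
#' which removes the curvature-dependent inward bias of a fixed 0.5 level.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param voxel_spacing um per axis.
#' @param sigma_um smoothing sigma in um (isotropic, default 0.7).
#' @return list with `area` (um^2) and `volume` (um^3, mesh-enclosed).
#' @export
mesh_surface <- function(mask, voxel_spacing, sigma_um = 0.7) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask cannot be meshed")
  ext <- apply(idx, 2, range)
  if (any(ext[2, ] - ext[1, ] < 1L)) {
    stop("mask thinner than 2 voxels along an axis; the isosurface is ",
         "degenerate — dilate the mask or image at higher resolution")
  }
  pad <- pmax(2L, ceiling(3 * sigma_um / voxel_spacing))
  lo <- pmax(ext[1, ] - pad, 1L)
  hi <- pmin(ext[2, ] + pad, dim(mask))
  m <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] * 1.0
  dim(m) <- hi - lo + 1L
  # zero border so the isosurface is closed even when the crop hits the array edge
  m[c(1, dim(m)[1]), , ] <- 0
  m[, c(1, dim(m)[2]), ] <- 0
  m[, , c(1, dim(m)[3])] <- 0
  f <- blur3d(m, sigma_um / voxel_spacing)
  iso <- resample_isotropic(f, voxel_spacing)
  voxvol_iso <- iso$spacing^3
  v_target <- sum(mask) * prod(voxel_spacing)
  k <- round(v_target / voxvol_iso)
  vals <- sort(as.numeric(iso$data), decreasing = TRUE)
  k <- min(max(k, 1), length(vals) - 1L)
  level <- min(max(vals[k], 1e-6), 1 - 1e-6)
  res <- .march_tets(as.numeric(iso$data), as.integer(dim(iso$data)),
                     iso$spacing, level)
  list(area = res[1], volume = res[2])
}

# voxels with at least one 6-neighbor outside the mask (or on the border)
surface_voxels <- function(mask) {
  inner <- mask
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    inner <- inner & shift_array3d(mask, o, fill = FALSE)
  }
  which(mask & !inner, arr.ind = TRUE)
}

# physical um coordinates of surface voxel centres
surface_points <- function(mask, voxel_spacing) {
  s <- surface_voxels(mask)
  sweep(s - 0.5, 2, voxel_spacing, "*")
}

# inertia-equivalent ellipsoid volume from second central moments of the
# voxel cloud: a uniform solid ellipsoid with semi-axes a has covariance
# diag(a^2 / 5), so a_i = sqrt(5 * lambda_i).
equivalent_ellipsoid_volume <- function(mask, voxel_spacing) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx - 0.5, 2, voxel_spacing, "*")
  cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts) # population moments
  # add the second moment of a voxel itself (uniform cube): spacing^2 / 12
  cv <- cv + diag(voxel_spacing^2 / 12)
  lam <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  (4 / 3) * pi * prod(sqrt(5 * lam))
}

#' Measure 3D morphometry of a single cell
#'
#' Computes the per-cell shape descriptor record in physical units:
#' volume (voxel count x voxel volume), surface area (isosurface mesh, see
#' [mesh_surface()]), sphericity `pi^(1/3) * (6 V)^(2/3) / A` (1 for a
#' perfect sphere), Feret diameter (maximum caliper over surface points,
#' via the convex hull), the volume of the inertia-equivalent ellipsoid, and
#' the volume:ellipsoid-volume ratio (a complexity measure).
#'
#' @param mask a [cell_mask()].
#' @param group optional group label (e.g. `"isolated"` / `"clustered"`).
#' @param sigma_um meshing smoothing sigma in um.
#' @return one-row data frame with columns `label, volume_um3,
#'   surface_area_um2, sphericity, feret_um, ellipsoid_volume_um3,
#'   volume_ellipsoid_ratio, mesh_volume_um3, group`.
#' @export
measure_cell <- function(mask, group = NA_character_, sigma_um = 0.7) {
  stopifnot(inherits(mask, "cell_mask"))
  sp <- mask$voxel_spacing
  volume <- sum(mask$mask) * prod(sp)
  mesh <- mesh_surface(mask$mask, sp, sigma_um)
  sphericity <- pi^(1 / 3) * (6 * volume)^(2 / 3) / mesh$area
  feret <- max_caliper(surface_points(mask$mask, sp))
  ve <- equivalent_ellipsoid_volume(mask$mask, sp)
  data.frame(
    label = mask$label,
    volume_um3 = volume,
    surface_area_um2 = mesh$area,
    sphericity = sphericity,
    feret_um = feret,
    ellipsoid_volume_um3 = ve,
    volume_ellipsoid_ratio = volume / ve,
    mesh_volume_um3 = mesh$volume,
    group = group,
    stringsAsFactors = FALSE
  )
}

#' Two-group comparison of a morphometric field
#'
#' Two-tailed two-sample t-test between the two groups of a per-cell record
#' table; pooled-variance (Student) by default, Welch behind the flag. Groups
#' with zero variance are reported with a warning rather than an error.
#'
#' @param records data frame with the measurement column and a group column.
#' @param field name of the measurement column.
#' @param group_field name of the group column (two levels required).
#' @param welch use the Welch (unequal-variance) variant.
#' @return one-row data frame: group means and standard deviations, `t`,
#'   `df`, `p_value`, `method`.
#' @export
compare_groups <- function(records, field, group_field = "group",
                           welch = FALSE) {
  g <- factor(records[[group_field]])
  if (nlevels(g) != 2L) stop("exactly two groups required")
  x <- records[[field]][g == levels(g)[1]]
  y <- records[[field]][g == levels(g)[2]]
  if (length(x) < 2L || length(y) < 2L) stop("both groups need n >= 2")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("a group has zero variance; t statistic may be degenerate")
  }
  if (sx == 0 && sy == 0) {
    tt <- list(statistic = if (mean(x) == mean(y)) 0 else
                 sign(mean(x) - mean(y)) * Inf,
               parameter = length(x) + length(y) - 2,
               p.value = if (mean(x) == mean(y)) 1 else 0)
  } else {
    tt <- stats::t.test(x, y, var.equal = !welch)
  }
  data.frame(
    field = field,
    group1 = levels(g)[1], n1 = length(x), mean1 = mean(x), sd1 = sx,
    group2 = levels(g)[2], n2 = length(y), mean2 = mean(y), sd2 = sy,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = unname(tt$p.value),
    method = if (welch) "welch" else "student",
    stringsAsFactors = FALSE
  )
}

#' Per-group ordinary least squares between two morphometric fields
#'
#' @param records per-cell data frame.
#' @param x_field,y_field column names to regress (`y ~ x`).
#' @param group_field optional grouping column; `NULL` fits one model.
#' @return data frame with one row per group: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
regress_fields <- function(records, x_field, y_field, group_field = NULL) {
  groups <- if (is.null(group_field)) list(all = records) else
    split(records, records[[group_field]])
  out <- lapply(names(groups), function(gn) {
    d <- groups[[gn]]
    if (nrow(d) < 3L) stop("group '", gn, "' has fewer than 3 records")
    x <- d[[x_field]]; y <- d[[y_field]]
    if (stats::sd(x) == 0) stop("zero variance in '", x_field, "' for group '", gn, "'")
    fit <- stats::lm(y ~ x)
    r2 <- if (stats::sd(y) == 0) 0 else
      suppressWarnings(summary(fit)$r.squared)
    data.frame(group = gn, slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, n = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
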