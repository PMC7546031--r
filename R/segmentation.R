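#' Binary 3D cell mask
#'
#' A logical raster aligned to its source image grid, with inherited voxel
#' spacing and the provenance of how it was produced (thresholds, structuring
#' radii) so every measurement is re-derivable.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param voxel_spacing um per axis `(z, y, x)`.
#' @param label integer label id.
#' @param provenance named list of processing parameters.
#' @return object of class `cell_mask`.
#' @export
cell_mask <- function(mask, voxel_spacing, label = 1L, provenance = list()) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!any(mask)) stop("cell mask must be non-empty")
  structure(list(mask = mask, voxel_spacing = as.numeric(voxel_spacing),
                 label = as.integer(label), provenance = provenance),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> label %d: %d voxels of %s, spacing (%g, %g, %g) um\n",
              x$label, sum(x$mask), paste(dim(x$mask), collapse = " x "),
              x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  invisible(x)
}

# array-level hysteresis: keep voxels >= low 26-connected to a voxel >= high
hysteresis_mask <- function(v, low, high) {
  if (low > high) stop("low threshold must be <= high")
  if (!any(v >= high)) stop("no voxel reaches the high threshold; empty mask")
  lab <- label_components(v >= low, 26L)
  seeds <- unique(lab[v >= high])
  seeds <- seeds[seeds > 0L]
  out <- array(lab %in% seeds, dim(v))
  out
}

#' Hysteresis segmentation of a 3D volume
#'
#' Voxels at or above `high` act as seeds; voxels at or above `low` are kept
#' iff 26-connected (in 3D) to a seed. With `low == high` this degenerates to
#' a simple threshold. In auto mode (`NULL` thresholds) `high` is the Otsu
#' threshold of the volume and `low = low_fraction * high`; the values used
#' are logged in the mask provenance.
#'
#' @param img a [vol_image()] (one frame/channel is taken) or a 3D array.
#' @param low,high absolute intensity thresholds, `0 <= low <= high`; `NULL`
#'   selects auto mode.
#' @param low_fraction auto-mode ratio `low / high` (default 0.5).
#' @param frame,channel which volume of a series to segment.
#' @param voxel_spacing required when `img` is a bare array.
#' @return a [cell_mask()] (possibly still multi-component; see [purify()]).
#' @export
hysteresis_segment <- function(img, low = NULL, high = NULL,
                               low_fraction = 0.5, frame = 1L, channel = 1L,
                               voxel_spacing = NULL) {
  if (inherits(img, "vol_image")) {
    v <- get_frame(img, frame, channel)
    voxel_spacing <- img$voxel_spacing
  } else {
    v <- img
    if (is.null(voxel_spacing)) stop("voxel_spacing required for array input")
  }
  auto <- is.null(high)
  if (auto) {
    high <- otsu_threshold(v)
    if (is.null(low)) low <- low_fraction * high
  }
  if (is.null(low)) low <- low_fraction * high
  if (low < 0 || low > high) stop("thresholds must satisfy 0 <= low <= high")
  m <- hysteresis_mask(v, low, high)
  cell_mask(m, voxel_spacing,
            provenance = list(step = "hysteresis_segment", low = low,
                              high = high, auto = auto))
}

# cavities = background (6-connected) not reaching the array border
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, 6L)
  d <- dim(mask)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  holes <- bg & !(array(lab %in% border, d))
  mask | holes
}

#' Refine a segmentation mask
#'
#' Fills interior cavities (background regions not 6-connected to the array
#' border), dilates by a voxel-isotropic ball, then smooths by morphological
#' opening followed by closing. With `smooth_radius = 0` the output is a
#' superset of the hole-filled input (dilation only grows).
#'
#' @param mask a [cell_mask()].
#' @param dilate_radius,smooth_radius structuring ball radii in voxels
#'   (0 disables the step).
#' @return the refined [cell_mask()].
#' @export
refine_mask <- function(mask, dilate_radius = 1, smooth_radius = 1) {
  stopifnot(inherits(mask, "cell_mask"))
  if (dilate_radius < 0 || smooth_radius < 0) stop("radii must be >= 0")
  m <- fill_holes(mask$mask)
  if (dilate_radius > 0) {
    m <- binary_dilate(m, ball_offsets(dilate_radius))
  }
  if (smooth_radius > 0) {
    off <- ball_offsets(smooth_radius)
    m <- binary_dilate(binary_erode(m, off), off) # opening
    m <- binary_erode(binary_dilate(m, off), off) # closing
  }
  if (!any(m)) stop("mask vanished during refinement")
  mask$mask <- m
  mask$provenance <- c(mask$provenance,
                       list(refine = list(dilate_radius = dilate_radius,
                                          smooth_radius = smooth_radius)))
  mask
}

#' Keep the largest connected component
#'
#' Retains only the largest 26-connected foreground component of the mask;
#' ties are broken deterministically in favor of the component containing the
#' smallest linear voxel index, and the tie-break is recorded in provenance.
#'
#' @param mask a [cell_mask()].
#' @return the purified [cell_mask()].
#' @export
purify <- function(mask) {
  stopifnot(inherits(mask, "cell_mask"))
  lab <- label_components(mask$mask, 26L)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) <= 1L) return(mask)
  biggest <- which(sizes == max(sizes))
  tie <- length(biggest) > 1L
  if (tie) {
    # component whose minimum linear index is smallest wins
    first_idx <- vapply(biggest, function(l) which(lab == l)[1L], integer(1))
    biggest <- biggest[which.min(first_idx)]
  }
  mask$mask <- array(lab == biggest, dim(mask$mask))
  mask$provenance <- c(mask$provenance,
                       list(purify = list(kept = as.integer(biggest),
                                          n_components = length(sizes),
                                          tie_break = tie)))
  mask
}

#' Apply a recorded exclusion mask
#'
#' Reproducible stand-in for manual per-slice trimming: voxels covered by the
#' exclusion raster are removed (`mask AND NOT exclusion`) and the result is
#' re-purified.
#'
#' @param mask a [cell_mask()].
#' @param exclusion logical 3D array on the same grid.
#' @return the trimmed [cell_mask()].
#' @export
apply_exclusion <- function(mask, exclusion) {
  stopifnot(inherits(mask, "cell_mask"))
  if (!identical(dim(exclusion), dim(mask$mask))) {
    stop("exclusion raster must share the mask grid")
  }
  m <- mask$mask & !exclusion
  if (!any(m)) stop("exclusion removes the entire mask")
  n_removed <- sum(mask$mask & exclusion)
  mask$mask <- m
  mask$provenance <- c(mask$provenance,
                       list(exclusion = list(n_removed = n_removed)))
  purify(mask)
}
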