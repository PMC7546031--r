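#' Volumetric image with physical voxel spacing
#'
#' The universal raster container of the pipeline: an intensity stack with
#' axis order fixed as `(t, c, z, y, x)` (time, channel, axial, row, column),
#' with singleton axes allowed, plus the voxel spacing in micrometres per axis
#' `(z, y, x)`. Voxel centres sit at `(index - 0.5) * spacing`, so an axis of
#' `n` voxels spans `[0, n * spacing]` um.
#'
#' @param data numeric array: 3D `(z, y, x)`, 4D `(t, z, y, x)` or 5D
#'   `(t, c, z, y, x)`; lower-dimensional inputs are promoted with singleton
#'   leading axes.
#' @param voxel_spacing numeric length-3, micrometres per voxel along
#'   `(z, y, x)`; all entries must be positive.
#' @return An object of class `vol_image`.
#' @export
vol_image <- function(data, voxel_spacing) {
  stopifnot(is.numeric(data) || is.logical(data))
  nd <- length(dim(data))
  if (is.null(dim(data)) || nd < 3 || nd > 5) {
    stop("`data` must be a 3D, 4D or 5D array")
  }
  if (nd == 3) dim(data) <- c(1L, 1L, dim(data))
  if (nd == 4) dim(data) <- c(dim(data)[1L], 1L, dim(data)[-1L])
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0)) {
    stop("`voxel_spacing` must be three positive values (z, y, x) in um")
  }
  structure(
    list(data = data, voxel_spacing = voxel_spacing, log = list()),
    class = "vol_image"
  )
}

#' @export
print.vol_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<vol_image> %d frame(s) x %d channel(s) x %d x %d x %d voxels, spacing (%g, %g, %g) um\n",
    d[1], d[2], d[3], d[4], d[5],
    x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  invisible(x)
}

#' Number of frames / channels of a volumetric image
#' @param img a [vol_image()]
#' @return integer count.
#' @export
n_frames <- function(img) {
  stopifnot(inherits(img, "vol_image"))
  dim(img$data)[1L]
}

#' @rdname n_frames
#' @export
n_channels <- function(img) {
  stopifnot(inherits(img, "vol_image"))
  dim(img$data)[2L]
}

#' Extract one 3D volume from a series
#'
#' @param img a [vol_image()]
#' @param frame,channel 1-based indices.
#' @return 3D numeric array `(z, y, x)`.
#' @export
get_frame <- function(img, frame = 1L, channel = 1L) {
  stopifnot(inherits(img, "vol_image"))
  d <- dim(img$data)
  if (frame < 1 || frame > d[1]) stop("frame index out of range")
  if (channel < 1 || channel > d[2]) stop("channel index out of range")
  out <- img$data[frame, channel, , , , drop = FALSE]
  dim(out) <- d[3:5]
  out
}

set_frame <- function(img, vol, frame = 1L, channel = 1L) {
  img$data[frame, channel, , , ] <- vol
  img
}

#' Physical coordinates of voxel centres
#'
#' @param dims integer length-3 grid shape `(z, y, x)`.
#' @param voxel_spacing um per voxel `(z, y, x)`.
#' @return list of three vectors of axis coordinates in um.
#' @keywords internal
voxel_axes <- function(dims, voxel_spacing) {
  lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * voxel_spacing[a])
}

# centroid of a logical 3D mask in physical um, (z, y, x)
mask_centroid <- function(mask, voxel_spacing) {
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask has no centroid")
  sub <- arrayInd(idx, dim(mask))
  (colMeans(sub) - 0.5) * voxel_spacing
}
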