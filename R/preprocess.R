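#' Preprocess an image series
#'
#' The standard chain applied uniformly (same parameters to every frame and
#' channel) before segmentation: a 2D median filter per z-slice to reduce
#' speckle noise, rolling-ball-style background subtraction realized as
#' grayscale opening with a square window per slice, then linear contrast rescaling
#' with percentile clipping.
#'
#' @param img a [vol_image()].
#' @param median_radius median filter radius in voxels (0 disables).
#' @param bg_radius background structuring radius in um, converted via the xy
#'   spacing so results are spacing-invariant (0 disables).
#' @param clip_percentiles length-2 strictly increasing percentiles in
#'   `[0, 100]`; intensities are clipped at these series-wide quantiles and
#'   rescaled to `[0, 1]`.
#' @return preprocessed [vol_image()].
#' @export
preprocess <- function(img, median_radius = 1L, bg_radius = 10,
                       clip_percentiles = c(0.1, 99.9)) {
  stopifnot(inherits(img, "vol_image"))
  if (median_radius < 0 || bg_radius < 0) stop("radii must be >= 0")
  if (length(clip_percentiles) != 2L ||
      clip_percentiles[1] >= clip_percentiles[2] ||
      clip_percentiles[1] < 0 || clip_percentiles[2] > 100) {
    stop("clip_percentiles must be strictly increasing within [0, 100]")
  }
  d <- dim(img$data)
  xy_spacing <- mean(img$voxel_spacing[2:3])
  bg_vox <- as.integer(round(bg_radius / xy_spacing))
  out <- img
  for (t in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      for (z in seq_len(d[3])) {
        sl <- matrix(img$data[t, ch, z, , ], d[4], d[5])
        if (median_radius > 0) {
          sl <- .median_filter_2d(sl, as.integer(median_radius))
        }
        if (bg_vox > 0) {
          bg <- .rank_filter_2d(.rank_filter_2d(sl, bg_vox, FALSE), bg_vox, TRUE)
          sl <- pmax(sl - bg, 0)
        }
        out$data[t, ch, z, , ] <- sl
      }
    }
  }
  q <- stats::quantile(out$data, probs = clip_percentiles / 100, names = FALSE)
  if (q[2] > q[1]) {
    out$data[] <- pmin(pmax((out$data - q[1]) / (q[2] - q[1]), 0), 1)
  } else {
    out$data[] <- 0
  }
  out$log <- c(out$log, list(list(
    step = "preprocess", median_radius = median_radius, bg_radius = bg_radius,
    clip_percentiles = clip_percentiles)))
  out
}

# phase correlation between two equally-shaped 3D volumes; returns the
# integer-voxel displacement d (z, y, x) such that mov ~ ref translated by d
phase_corr_shift <- function(ref, mov) {
  F1 <- stats::fft(ref)
  F2 <- stats::fft(mov)
  X <- F1 * Conj(F2)
  m <- Mod(X)
  X <- X / pmax(m, 1e-12)
  r <- Re(stats::fft(X, inverse = TRUE))
  peak <- arrayInd(which.max(r), dim(r)) - 1L
  d <- dim(ref)
  s <- ifelse(peak > d / 2, peak - d, peak)
  -as.integer(s)
}

#' Correct whole-field drift in a time series
#'
#' Estimates a per-frame integer-voxel translation against frame 1 by 3D
#' phase correlation on the reference channel, then applies the inverse
#' translation to every channel (out-of-frame voxels zero-filled).
#'
#' @param img a [vol_image()] with at least two frames.
#' @param reference_channel channel used for estimation; the identical
#'   translation is applied to all channels.
#' @return list with `image` (the registered [vol_image()]) and `drift`
#'   (data frame `frame, dz, dy, dx`: estimated content displacement of each
#'   frame relative to frame 1, in voxels; frame 1 is `(0, 0, 0)`).
#' @export
correct_drift <- function(img, reference_channel = 1L) {
  stopifnot(inherits(img, "vol_image"))
  d <- dim(img$data)
  if (d[1] < 2L) stop("drift correction needs at least 2 frames")
  ref <- get_frame(img, 1L, reference_channel)
  if (all(ref == 0)) stop("frame 1 is all zero; phase correlation undefined")
  shifts <- matrix(0L, d[1], 3L)
  out <- img
  for (t in 2:d[1]) {
    mov <- get_frame(img, t, reference_channel)
    if (all(mov == 0)) {
      stop(sprintf("frame %d is all zero; phase correlation undefined", t))
    }
    shifts[t, ] <- phase_corr_shift(ref, mov)
    for (ch in seq_len(d[2])) {
      vol <- get_frame(img, t, ch)
      out$data[t, ch, , , ] <- shift_array3d(vol, -shifts[t, ], fill = 0)
    }
  }
  drift <- data.frame(frame = seq_len(d[1]), dz = shifts[, 1],
                      dy = shifts[, 2], dx = shifts[, 3])
  out$log <- c(out$log, list(list(step = "correct_drift",
                                  reference_channel = reference_channel)))
  list(image = out, drift = drift)
}

#' Remove frames or z-slices from a series
#'
#' Reproducible replacement for ad-hoc removal of blurred slices: the removed
#' indices are recorded in the image log.
#'
#' @param img a [vol_image()].
#' @param indices indices to remove (unique, in range); empty for identity.
#' @param axis `"t"` to drop time points, `"z"` to drop z-slices.
#' @return the reduced [vol_image()].
#' @export
exclude_frames <- function(img, indices, axis = c("t", "z")) {
  stopifnot(inherits(img, "vol_image"))
  axis <- match.arg(axis)
  indices <- as.integer(indices)
  if (length(indices) == 0L) return(img)
  if (anyDuplicated(indices)) stop("duplicate indices in exclusion list")
  ax <- if (axis == "t") 1L else 3L
  n <- dim(img$data)[ax]
  if (any(indices < 1L | indices > n)) stop("exclusion index out of range")
  if (length(indices) >= n) stop("cannot remove every ", axis, " index")
  keep <- setdiff(seq_len(n), indices)
  img$data <- if (axis == "t") {
    img$data[keep, , , , , drop = FALSE]
  } else {
    img$data[, , keep, , , drop = FALSE]
  }
  img$log <- c(img$log, list(list(step = "exclude_frames", axis = axis,
                                  removed = indices)))
  img
}
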