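#' Write a volumetric series as a multi-page TIFF
#'
#' Pages are written in `(channel, z, frame)` order (channel fastest), the
#' hyperstack page order of common ImageJ-style stacks. Samples are stored as
#' 32-bit float after division by a recorded intensity scale (TIFF float
#' samples are confined to `[0, 1]` by the writer); the scale, voxel spacing
#' and axis sizes go to a JSON sidecar `<path>.json`, which [read_stack()]
#' uses to restore the stack exactly (at 32-bit float precision).
#'
#' @param img a [vol_image()].
#' @param path output TIFF path; the sidecar is written at `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(img, path) {
  stopifnot(inherits(img, "vol_image"))
  d <- dim(img$data)
  scale <- max(img$data, 1e-12)
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 0L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[3])) {
      for (ch in seq_len(d[2])) {
        k <- k + 1L
        pages[[k]] <- matrix(img$data[t, ch, z, , ] / scale, d[4], d[5])
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    axes = "tczyx",
    shape = as.integer(d),
    voxel_spacing_um = img$voxel_spacing,
    intensity_scale = scale,
    unit = "micron"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a TIFF stack into a volumetric image
#'
#' Looks for the JSON sidecar written by [write_stack()]; without it, the
#' stack is read as a single-frame single-channel z-stack and `voxel_spacing`
#' (plus optionally `shape`) must be supplied, otherwise reading errors.
#'
#' @param path TIFF file path.
#' @param voxel_spacing optional um per axis `(z, y, x)` override; required
#'   when no sidecar metadata exists.
#' @return a [vol_image()].
#' @export
read_stack <- function(path, voxel_spacing = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    d <- as.integer(meta$shape)
    spacing <- if (!is.null(voxel_spacing)) as.numeric(voxel_spacing) else
      as.numeric(meta$voxel_spacing_um)
    scale <- as.numeric(meta$intensity_scale)
  } else {
    if (is.null(voxel_spacing)) {
      stop("no voxel spacing metadata found for ", path,
           "; supply `voxel_spacing` explicitly")
    }
    d <- c(1L, 1L, length(pages), dim(pages[[1]])[1], dim(pages[[1]])[2])
    spacing <- as.numeric(voxel_spacing)
    scale <- 1
  }
  if (length(pages) != d[1] * d[2] * d[3]) {
    stop("page count does not match recorded shape for ", path)
  }
  data <- array(0, d)
  k <- 0L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[3])) {
      for (ch in seq_len(d[2])) {
        k <- k + 1L
        p <- pages[[k]]
        if (length(dim(p)) == 3L) p <- p[, , 1L]
        data[t, ch, z, , ] <- p * scale
      }
    }
  }
  vol_image(data, spacing)
}
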