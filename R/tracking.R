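#' Extract per-frame cell centres from masks
#'
#' Centres are intensity-independent binary centroids in physical um.
#'
#' @param masks_per_cell named list: per cell, a list with one entry per
#'   frame, each a [cell_mask()] or `NULL` (absent).
#' @return tidy data frame `cell_id, frame, present, z, y, x` (um; NA when
#'   absent).
#' @export
extract_centers <- function(masks_per_cell) {
  rows <- list()
  for (cn in names(masks_per_cell)) {
    per_frame <- masks_per_cell[[cn]]
    for (t in seq_along(per_frame)) {
      m <- per_frame[[t]]
      if (is.null(m)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cn, frame = t, present = FALSE,
          z = NA_real_, y = NA_real_, x = NA_real_)
      } else {
        stopifnot(inherits(m, "cell_mask"))
        if (!any(m$mask)) stop("empty mask for cell ", cn, " frame ", t)
        ctr <- mask_centroid(m$mask, m$voxel_spacing)
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = cn, frame = t, present = TRUE,
          z = ctr[1], y = ctr[2], x = ctr[3])
      }
    }
  }
  do.call(rbind, rows)
}

#' Normalize trajectories to a reference cell
#'
#' Subtracts the reference cell's centre from every cell per frame, placing
#' the reference at the origin — removing whole-field motion so relative
#' rearrangement is visible.
#'
#' @param tracks data frame from [extract_centers()].
#' @param reference_id cell id of the reference; must be present at every
#'   frame.
#' @return tracks with `z, y, x` in the reference frame.
#' @export
normalize_to_reference <- function(tracks, reference_id) {
  ref <- tracks[tracks$cell_id == reference_id, ]
  if (nrow(ref) == 0L) stop("reference cell not found: ", reference_id)
  if (!all(ref$present)) {
    stop("reference cell absent at frame(s) ",
         paste(ref$frame[!ref$present], collapse = ", "))
  }
  ref <- ref[order(ref$frame), ]
  out <- tracks
  for (t in ref$frame) {
    sel <- out$frame == t
    out$z[sel] <- out$z[sel] - ref$z[ref$frame == t]
    out$y[sel] <- out$y[sel] - ref$y[ref$frame == t]
    out$x[sel] <- out$x[sel] - ref$x[ref$frame == t]
  }
  out
}

#' Centre-to-centre distance of a cell pair over time
#'
#' @param tracks data frame from [extract_centers()].
#' @param pair character length-2 of cell ids; order-symmetric.
#' @return list with `series` (data frame `frame, distance_um`), `delta`
#'   (last minus first distance, um) and `tau` (Kendall rank correlation of
#'   distance with time, a monotonic-trend summary).
#' @export
distance_series <- function(tracks, pair) {
  stopifnot(length(pair) == 2L)
  pair <- sort(as.character(pair))
  a <- tracks[tracks$cell_id == pair[1] & tracks$present, ]
  b <- tracks[tracks$cell_id == pair[2] & tracks$present, ]
  common <- intersect(a$frame, b$frame)
  if (length(common) < 2L) stop("need >= 2 common frames for a pair")
  common <- sort(common)
  a <- a[match(common, a$frame), ]
  b <- b[match(common, b$frame), ]
  d <- sqrt((a$z - b$z)^2 + (a$y - b$y)^2 + (a$x - b$x)^2)
  tau <- if (stats::sd(d) == 0) 0 else
    suppressWarnings(stats::cor(common, d, method = "kendall"))
  list(series = data.frame(frame = common, distance_um = d),
       delta = d[length(d)] - d[1L], tau = tau)
}

#' Convex-hull clustering volume of cell centres
#'
#' The volume of the minimal convex polyhedron containing all present cell
#' centres at a frame — the clustering metric that shrinks as cells coalesce.
#' Fewer than 4 non-coplanar centres give volume 0 with the degeneracy
#' flagged.
#'
#' @param tracks data frame from [extract_centers()].
#' @param frame frame index; default all frames.
#' @return data frame `frame, hull_volume_um3, n_cells, degenerate`.
#' @export
hull_metric <- function(tracks, frame = NULL) {
  frames <- if (is.null(frame)) sort(unique(tracks$frame)) else frame
  out <- lapply(frames, function(t) {
    pres <- tracks[tracks$frame == t & tracks$present, ]
    if (nrow(pres) == 0L) stop("no present cells at frame ", t)
    pts <- as.matrix(pres[, c("z", "y", "x")])
    h <- convex_hull_3d(pts)
    data.frame(frame = t, hull_volume_um3 = h$volume,
               n_cells = nrow(pres), degenerate = h$degenerate)
  })
  do.call(rbind, out)
}
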