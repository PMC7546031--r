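#' Parameters of filopodium detection and dynamics classification
#'
#' Defaults follow the quantification conventions for islet-cell protrusions:
#' a protrusion counts as a filopodium from 1.0 um length; a dynamic event is
#' a > 50% relative length change (or an appearance/disappearance); the
#' analysis window is 20 minutes sampled at 2-minute intervals (11 frames).
#'
#' @param min_length um; protrusions below this length are treated as absent.
#' @param change_fraction relative length-change threshold for an event and
#'   for the stability bound.
#' @param series_duration analysis window in minutes.
#' @param frame_interval minutes between frames.
#' @param gate_radius um; maximum base-point displacement for frame-to-frame
#'   track linking.
#' @param tip_separation um; minimum separation between distinct tips of a
#'   branched protrusion.
#' @param low_fraction hysteresis low/high ratio for the whole-cell
#'   (protrusion-inclusive) segmentation; lower than the body default so thin
#'   dim shafts are kept.
#' @param body_opening_radius um; physical-radius morphological opening applied to the
#'   body mask before subtraction, so shafts brighter than the body threshold
#'   still trace from the body surface (the opening removes structures
#'   thinner than this radius from the body).
#' @param body_margin um; guard margin dilated onto the body before
#'   subtraction so the point-spread halo at the body surface is not read as
#'   protrusions; added back to traced lengths.
#' @param min_component_voxels protrusion components smaller than this are
#'   discarded as noise.
#' @param min_track_frames tracks detected in fewer frames than this are
#'   dropped as flicker noise (scripted and real filopodia persist; isolated
#'   single-frame detections are typically segmentation noise).
#' @param presmooth_sigma um; light isotropic Gaussian smoothing applied to
#'   each frame before series analysis (see [analyze_filopodia_series()]),
#'   suppressing frame-to-frame tip flicker; 0 disables.
#' @param gap_close_frames interior detection gaps up to this many frames are
#'   linearly interpolated before classification; a 2-minute dropout of an
#'   otherwise continuous track is detector flicker, not a disappearance.
#' @param min_radiality minimum fraction of a trace's base-to-tip
#'   displacement that points radially away from the cell body centroid;
#'   protrusions extend outward, while point-spread halo spurs run along the
#'   body surface and are rejected. Set 0 to disable (e.g. for strongly
#'   curved protrusions).
#' @return object of class `dynamics_params`.
#' @export
dynamics_params <- function(min_length = 1.0, change_fraction = 0.5,
                            series_duration = 20, frame_interval = 2,
                            gate_radius = 2.0, tip_separation = 2.5,
                            low_fraction = 0.2, body_opening_radius = 1.5,
                            body_margin = 0.6, min_component_voxels = 8L,
                            min_track_frames = 2L, min_radiality = 0.4,
                            gap_close_frames = 1L, presmooth_sigma = 0.3) {
  if (min_length <= 0) stop("min_length must be > 0")
  if (change_fraction <= 0) stop("change_fraction must be > 0")
  structure(list(min_length = min_length, change_fraction = change_fraction,
                 series_duration = series_duration,
                 frame_interval = frame_interval, gate_radius = gate_radius,
                 tip_separation = tip_separation, low_fraction = low_fraction,
                 body_opening_radius = body_opening_radius,
                 body_margin = body_margin,
                 min_component_voxels = as.integer(min_component_voxels),
                 min_track_frames = as.integer(min_track_frames),
                 min_radiality = min_radiality,
                 gap_close_frames = as.integer(gap_close_frames),
                 presmooth_sigma = presmooth_sigma),
            class = "dynamics_params")
}

# number of frames in the analysis window
window_frames <- function(params) {
  as.integer(round(params$series_duration / params$frame_interval)) + 1L
}

#' Trace filopodia of one cell in one frame
#'
#' Segments the whole cell including protrusions (hysteresis with a lower low
#' threshold), subtracts the body mask to get protrusion voxels, and traces
#' each protrusion by geodesic shortest paths: multi-source Dijkstra from the
#' body-adjacent base voxels through the protrusion voxel graph
#' (26-connectivity, physical edge lengths), tips at local maxima of geodesic
#' distance (non-maximum suppressed at `tip_separation`), the trace being the
#' shortest path from tip back to base. Branches shorter than the voxel
#' diagonal are discarded as noise; a branched protrusion yields one trace
#' per tip, sharing the trunk.
#'
#' @param img a [vol_image()] (one frame taken) or 3D array.
#' @param body_mask a [cell_mask()] of the cell body in the same frame.
#' @param params a [dynamics_params()].
#' @param low,high optional absolute hysteresis thresholds for the whole-cell
#'   segmentation; default auto (Otsu high, `low_fraction * high` low).
#' @param frame,channel series indices when `img` is a [vol_image()].
#' @return list of traces, each a list with `path` (`k x 3` matrix of um
#'   coordinates base -> tip), `length` (um), `base_point`, `tip_point`;
#'   empty list when the cell has no protrusions.
#' @export
trace_filopodia <- function(img, body_mask, params = dynamics_params(),
                            low = NULL, high = NULL, frame = 1L,
                            channel = 1L) {
  stopifnot(inherits(body_mask, "cell_mask"))
  if (inherits(img, "vol_image")) {
    v <- get_frame(img, frame, channel)
    sp <- img$voxel_spacing
  } else {
    v <- img
    sp <- body_mask$voxel_spacing
  }
  if (!identical(dim(v), dim(body_mask$mask))) {
    stop("image and body mask grids differ")
  }
  if (is.null(high)) high <- otsu_threshold(v)
  if (is.null(low)) low <- params$low_fraction * high
  whole <- tryCatch(hysteresis_mask(v, low, high),
                    error = function(e) NULL)
  if (is.null(whole)) return(list())
  # open the body so thin shafts brighter than the body threshold are not
  # swallowed by it: tracing must start at the body surface proper
  body <- body_mask$mask
  if (params$body_opening_radius > 0) {
    off <- ball_offsets_um(params$body_opening_radius, sp)
    body <- binary_dilate(binary_erode(body, off), off)
    if (!any(body)) body <- body_mask$mask
  }
  # guard margin: grow the body so the point-spread halo hugging its surface
  # is not mistaken for protrusions; the margin is added back to the length
  if (params$body_margin > 0) {
    body <- binary_dilate(body, ball_offsets_um(params$body_margin, sp))
  }
  prot <- whole & !body
  if (!any(prot)) return(list())
  body_center <- mask_centroid(body_mask$mask, sp)
  near_body <- binary_dilate(body, ball_offsets(sqrt(3)))
  lab <- label_components(prot, 26L)
  d <- dim(v)
  diag_len <- sqrt(sum(sp^2))
  traces <- list()
  for (l in setdiff(unique(lab[near_body & prot]), 0L)) {
    comp <- lab == l
    if (sum(comp) < params$min_component_voxels) next
    sources <- which(comp & near_body)
    if (!length(sources)) next
    geo <- .geodesic_paths(as.logical(comp), as.integer(d), sp, sources - 1L)
    dist <- array(geo$dist, d)
    pred <- geo$pred
    reach <- is.finite(dist) & comp
    if (!any(reach)) next
    dist[!reach] <- -Inf # so unreachable voxels never dominate a maximum test
    # tips: local maxima of geodesic distance within the component
    is_max <- reach
    for (o in as.data.frame(t(ball_offsets(sqrt(3))))) {
      if (all(o == 0)) next
      nb <- shift_array3d(dist, as.numeric(o), fill = -Inf)
      is_max <- is_max & (dist >= nb)
    }
    # the discard threshold applies to the reported length (geodesic run
    # plus the guard margin it stands in for), not the raw run
    cand <- which(is_max & (dist + params$body_margin) >= diag_len)
    if (!length(cand)) next
    cand <- cand[order(dist[cand], decreasing = TRUE)]
    cand_pts <- sweep(arrayInd(cand, d) - 0.5, 2, sp, "*")
    path_pts <- NULL # voxels of already-extracted paths, um
    for (i in seq_along(cand)) {
      p <- cand_pts[i, ]
      # suppress side bumps: a genuine new tip must lie away from every
      # already-traced path, not merely away from accepted tips
      if (!is.null(path_pts) &&
          min(sqrt(colSums((t(path_pts) - p)^2))) <= params$tip_separation) {
        next
      }
      tp <- cand[i]
      path_idx <- tp
      cur <- tp
      while (pred[cur] >= 0L) {
        cur <- pred[cur] + 1L
        path_idx <- c(cur, path_idx)
      }
      if (length(path_idx) < 3L) next # single-step stubs are raster noise
      coords <- sweep(arrayInd(path_idx, d) - 0.5, 2, sp, "*")
      path_pts <- rbind(path_pts, coords)
      if (params$min_radiality > 0) {
        disp <- coords[nrow(coords), ] - coords[1L, ]
        outward <- coords[1L, ] - body_center
        outward <- outward / max(sqrt(sum(outward^2)), 1e-9)
        radiality <- sum(disp * outward) / max(sqrt(sum(disp^2)), 1e-9)
        if (radiality < params$min_radiality) next
      }
      traces[[length(traces) + 1L]] <- list(
        path = coords,
        length = dist[tp] + params$body_margin,
        base_point = coords[1L, ],
        tip_point = coords[nrow(coords), ],
        component = l)
    }
  }
  dedupe_traces(traces, sp)
}

# Axial blur can split one filopodium into extra traces: parallel copies in
# adjacent z-planes, or short halo spurs rooted at the same base — always in
# a different connected component, so in-component tip suppression cannot see
# them. Keep the longest trace of any near-coincident set: a shorter trace
# from another component is dropped when its base lies within
# `base_radius` of a kept trace's base, or when most of its path runs within
# one z-spacing (plus slack) of a kept path. Branch traces (same component,
# shared trunk) are never deduplicated.
dedupe_traces <- function(traces, sp, overlap_radius = 1.3 * max(sp),
                          overlap_fraction = 0.6, base_radius = 1.6) {
  if (length(traces) < 2L) return(traces)
  ord <- order(vapply(traces, `[[`, numeric(1), "length"), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    tr <- traces[[i]]
    dup <- FALSE
    for (k in kept) {
      if (k$component == tr$component) next
      if (sqrt(sum((k$base_point - tr$base_point)^2)) <= base_radius) {
        dup <- TRUE
        break
      }
      near <- vapply(seq_len(nrow(tr$path)), function(j) {
        min(sqrt(colSums((t(k$path) - tr$path[j, ])^2))) <= overlap_radius
      }, logical(1))
      if (mean(near) >= overlap_fraction) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- tr
  }
  kept
}

#' Link per-frame filopodium traces into tracks
#'
#' Greedy nearest-base-point matching frame to frame: candidate pairs within
#' the gate radius are assigned in order of increasing base distance (ties
#' broken by closest length); unmatched traces open new tracks; a track with
#' no match in a frame records absence at that frame.
#'
#' @param traces_per_frame list (one element per frame) of trace lists as
#'   returned by [trace_filopodia()].
#' @param params a [dynamics_params()].
#' @return list of tracks, each with `track_id`, `frames` (frames present),
#'   `lengths` (um per present frame), `base_points` (matrix).
#' @export
link_tracks <- function(traces_per_frame, params = dynamics_params()) {
  tracks <- list()
  last_base <- NULL   # matrix of active track last base points
  last_len <- numeric(0)
  track_of <- integer(0) # row -> track index
  for (t in seq_along(traces_per_frame)) {
    traces <- traces_per_frame[[t]]
    if (length(traces)) {
      bases <- do.call(rbind, lapply(traces, `[[`, "base_point"))
      lens <- vapply(traces, `[[`, numeric(1), "length")
    } else {
      bases <- NULL
      lens <- numeric(0)
    }
    assigned_trace <- rep(FALSE, length(traces))
    if (!is.null(last_base) && length(traces)) {
      cand <- expand.grid(tr = seq_len(nrow(last_base)),
                          nw = seq_along(traces))
      dd <- sqrt(rowSums((last_base[cand$tr, , drop = FALSE] -
                            bases[cand$nw, , drop = FALSE])^2))
      dl <- abs(last_len[cand$tr] - lens[cand$nw])
      ok <- dd <= params$gate_radius
      cand <- cand[ok, , drop = FALSE]
      ord <- order(dd[ok], dl[ok])
      used_track <- rep(FALSE, nrow(last_base))
      for (i in ord) {
        tr <- cand$tr[i]; nw <- cand$nw[i]
        if (used_track[tr] || assigned_trace[nw]) next
        used_track[tr] <- TRUE
        assigned_trace[nw] <- TRUE
        ti <- track_of[tr]
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, t)
        tracks[[ti]]$lengths <- c(tracks[[ti]]$lengths, lens[nw])
        tracks[[ti]]$base_points <- rbind(tracks[[ti]]$base_points,
                                          bases[nw, ])
        last_base[tr, ] <- bases[nw, ]
        last_len[tr] <- lens[nw]
      }
    }
    for (nw in which(!assigned_trace)) {
      tracks[[length(tracks) + 1L]] <- list(
        track_id = length(tracks) + 1L, frames = t, lengths = lens[nw],
        base_points = matrix(bases[nw, ], 1L, 3L))
      last_base <- rbind(last_base, bases[nw, ])
      last_len <- c(last_len, lens[nw])
      track_of <- c(track_of, length(tracks))
    }
  }
  tracks
}

# per-frame length vector of a track over frames 1..n (0 = absent)
track_lengths <- function(track, n_frames) {
  out <- numeric(n_frames)
  keep <- track$frames <= n_frames
  out[track$frames[keep]] <- track$lengths[keep]
  out
}

# interpolate interior runs of zeros up to `max_gap` frames long when flanked
# by detections; leading/trailing absence is preserved
close_track_gaps <- function(lengths, max_gap = 1L) {
  if (max_gap <= 0L) return(lengths)
  present <- which(lengths > 0)
  if (length(present) < 2L) return(lengths)
  for (k in seq_len(length(present) - 1L)) {
    a <- present[k]
    b <- present[k + 1L]
    gap <- b - a - 1L
    if (gap >= 1L && gap <= max_gap) {
      lengths[(a + 1L):(b - 1L)] <- lengths[a] +
        (lengths[b] - lengths[a]) * seq_len(gap) / (gap + 1L)
    }
  }
  lengths
}

#' Classify the dynamics of one filopodium track
#'
#' Applies the shared event rules (see [truth_event_labels()]) to the track's
#' per-frame length series over the analysis window: a dynamic event per
#' appearance, disappearance or > `change_fraction` relative length change
#' between consecutive frames; stable iff present at every frame with total
#' relative length range within `change_fraction`.
#'
#' @param track a track from [link_tracks()].
#' @param params a [dynamics_params()].
#' @param n_frames number of frames in the series.
#' @return list with `dynamic_events` and `stable`.
#' @export
classify_dynamics <- function(track, params = dynamics_params(),
                              n_frames = window_frames(params)) {
  nw <- window_frames(params)
  if (nw > n_frames) {
    stop(sprintf("analysis window (%d frames) exceeds the series (%d frames)",
                 nw, n_frames))
  }
  lengths <- close_track_gaps(track_lengths(track, nw),
                              params$gap_close_frames)
  dynamics_rules(lengths, params$min_length, params$change_fraction)
}

#' Summarize filopodial dynamics per cell and compare groups
#'
#' @param tracks_per_cell named list: one list of tracks (from
#'   [link_tracks()]) per cell.
#' @param group_labels named character vector mapping cell name to group.
#' @param params a [dynamics_params()].
#' @param n_frames frames in the series.
#' @return list with `per_cell` (data frame cell, group, dynamic_events,
#'   stable_filopodia) and `tests` (group comparisons of both counts via
#'   [compare_groups()], `NULL` when fewer than two cells per group).
#' @export
summarize_dynamics <- function(tracks_per_cell, group_labels,
                               params = dynamics_params(),
                               n_frames = window_frames(params)) {
  if (!length(tracks_per_cell)) stop("at least one cell required")
  rows <- lapply(names(tracks_per_cell), function(cn) {
    tracks <- tracks_per_cell[[cn]]
    if (length(tracks)) {
      cls <- lapply(tracks, classify_dynamics, params = params,
                    n_frames = n_frames)
      ev <- sum(vapply(cls, `[[`, integer(1), "dynamic_events"))
      st <- sum(vapply(cls, `[[`, logical(1), "stable"))
    } else {
      ev <- 0L; st <- 0L
    }
    data.frame(cell = cn, group = unname(group_labels[cn]),
               dynamic_events = ev, stable_filopodia = st,
               stringsAsFactors = FALSE)
  })
  per_cell <- do.call(rbind, rows)
  tests <- NULL
  tab <- table(per_cell$group)
  if (length(tab) == 2L && all(tab >= 2L)) {
    tests <- rbind(compare_groups(per_cell, "dynamic_events"),
                   compare_groups(per_cell, "stable_filopodia"))
  }
  list(per_cell = per_cell, tests = tests)
}

#' Tidy data frame of traces across frames
#'
#' @param traces_per_frame list of per-frame trace lists.
#' @return data frame with `frame, trace, length_um, base_z, base_y, base_x`.
#' @export
traces_to_df <- function(traces_per_frame) {
  rows <- list()
  for (t in seq_along(traces_per_frame)) {
    for (i in seq_along(traces_per_frame[[t]])) {
      tr <- traces_per_frame[[t]][[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        frame = t, trace = i, length_um = tr$length,
        base_z = tr$base_point[1], base_y = tr$base_point[2],
        base_x = tr$base_point[3])
    }
  }
  if (!length(rows)) {
    return(data.frame(frame = integer(), trace = integer(),
                      length_um = numeric(), base_z = numeric(),
                      base_y = numeric(), base_x = numeric()))
  }
  do.call(rbind, rows)
}
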