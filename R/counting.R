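#' Count double-positive cells from two channels of point annotations
#'
#' A reference-channel point (e.g. GFP+) is double-positive iff a
#' second-channel point (e.g. mCherry+) lies within `match_radius`. Points of
#' one channel closer together than half the match radius are considered
#' duplicate annotations of one cell and merged with a warning.
#'
#' @param points_reference,points_second `n x 3` matrices of point positions
#'   in um `(z, y, x)`; annotations or detected peaks.
#' @param match_radius um; default 3 (about half a nuclear diameter).
#' @return data frame `n_reference, n_double, fraction`.
#' @export
count_cells <- function(points_reference, points_second, match_radius = 3) {
  if (match_radius <= 0) stop("match_radius must be > 0")
  points_reference <- merge_close_points(as_points(points_reference),
                                         match_radius / 2, "reference")
  points_second <- merge_close_points(as_points(points_second),
                                      match_radius / 2, "second")
  n_ref <- nrow(points_reference)
  if (n_ref == 0L) stop("no reference points")
  n_double <- 0L
  if (nrow(points_second)) {
    for (i in seq_len(n_ref)) {
      d <- sqrt(colSums((t(points_second) - points_reference[i, ])^2))
      if (any(d <= match_radius)) n_double <- n_double + 1L
    }
  }
  data.frame(n_reference = n_ref, n_double = n_double,
             fraction = n_double / n_ref)
}

as_points <- function(p) {
  if (is.null(p) || length(p) == 0L) return(matrix(numeric(0), 0, 3))
  p <- as.matrix(p)
  stopifnot(ncol(p) == 3L)
  p
}

merge_close_points <- function(p, radius, what) {
  if (nrow(p) < 2L) return(p)
  keep <- logical(nrow(p))
  merged <- 0L
  for (i in seq_len(nrow(p))) {
    if (any(keep)) {
      d <- sqrt(colSums((t(p[keep, , drop = FALSE]) - p[i, ])^2))
      if (any(d < radius)) { merged <- merged + 1L; next }
    }
    keep[i] <- TRUE
  }
  if (merged > 0L) {
    warning(sprintf("merged %d duplicate %s-channel point(s) within %.2f um",
                    merged, what, radius))
  }
  p[keep, , drop = FALSE]
}

#' Detect cells as local intensity maxima
#'
#' Automated stand-in for manual point annotation on synthetic or
#' well-separated data: voxels above a threshold that are 26-neighborhood
#' local maxima, non-maximum suppressed at `min_distance`.
#'
#' @param v 3D intensity array `(z, y, x)` or [vol_image()].
#' @param voxel_spacing um per axis (taken from the image if a
#'   [vol_image()]).
#' @param min_distance um between accepted peaks.
#' @param threshold absolute intensity; default Otsu.
#' @param frame,channel indices into a series.
#' @return matrix of peak positions in um `(z, y, x)`, brightest first.
#' @export
detect_peaks <- function(v, voxel_spacing = NULL, min_distance = 3,
                         threshold = NULL, frame = 1L, channel = 1L) {
  if (inherits(v, "vol_image")) {
    voxel_spacing <- v$voxel_spacing
    v <- get_frame(v, frame, channel)
  }
  if (is.null(voxel_spacing)) stop("voxel_spacing required for array input")
  if (is.null(threshold)) threshold <- otsu_threshold(v)
  is_max <- v > threshold
  for (o in as.data.frame(t(ball_offsets(sqrt(3))))) {
    if (all(o == 0)) next
    is_max <- is_max & (v >= shift_array3d(v, as.numeric(o), fill = -Inf))
  }
  cand <- which(is_max)
  if (!length(cand)) return(matrix(numeric(0), 0, 3))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  pts <- sweep(arrayInd(cand, dim(v)) - 0.5, 2, voxel_spacing, "*")
  keep <- integer(0)
  for (i in seq_len(nrow(pts))) {
    if (!length(keep) ||
        min(sqrt(colSums((t(pts[keep, , drop = FALSE]) - pts[i, ])^2))) >=
        min_distance) {
      keep <- c(keep, i)
    }
  }
  pts[keep, , drop = FALSE]
}

#' Assemble a run report
#'
#' Bundles the outputs of any subset of pipeline stages into a single
#' provenance-carrying report: a JSON body (deterministic given the same
#' inputs; timestamps are excluded from the body) plus one CSV per tabular
#' stage. Missing stages are flagged as absent rather than failing.
#'
#' @param stages named list of stage outputs (data frames or lists); `NULL`
#'   entries are recorded as absent.
#' @param sample_id optional sample identifier; if stage outputs carry a
#'   `sample_id` attribute the values must agree.
#' @param dir optional output directory; when given, `report.json` and the
#'   stage CSVs are written there.
#' @param params optional named list of run parameters to record.
#' @return the report object (list), invisibly when written.
#' @export
build_report <- function(stages, sample_id = NULL, dir = NULL,
                         params = list()) {
  if (!length(stages) || all(vapply(stages, is.null, logical(1)))) {
    stop("at least one stage output required")
  }
  ids <- unique(c(sample_id, unlist(lapply(stages, attr, "sample_id"))))
  if (length(ids) > 1L) {
    stop("conflicting sample ids across stages: ", paste(ids, collapse = ", "))
  }
  present <- names(stages)[!vapply(stages, is.null, logical(1))]
  absent <- setdiff(names(stages), present)
  report <- list(
    sample_id = if (length(ids)) ids else NA,
    software = list(package = "isletmorph",
                    version = as.character(utils::packageVersion("isletmorph"))),
    params = params,
    stages_present = present,
    stages_absent = absent,
    files = list()
  )
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (sn in present) {
      x <- stages[[sn]]
      if (is.data.frame(x)) {
        f <- file.path(dir, paste0(sn, ".csv"))
        utils::write.csv(x, f, row.names = FALSE)
        report$files[[sn]] <- basename(f)
      }
    }
    report$tables <- stages[present][!vapply(stages[present], is.data.frame,
                                             logical(1))]
    jsonlite::write_json(report, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(report))
  }
  report$tables <- stages[present]
  report
}
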