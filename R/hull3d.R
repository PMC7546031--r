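# 3D convex hull by the quickhull algorithm, pure R with vectorized
# point-face distance tests. Used for the maximum-caliper (Feret) diameter and
# for the convex-hull clustering volume.

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# plane through face (a, b, c) of `pts`; unit normal + offset
face_plane <- function(pts, f) {
  a <- pts[f[1], ]
  n <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
  len <- sqrt(sum(n^2))
  if (len < .Machine$double.eps) return(NULL)
  n <- n / len
  list(n = n, d = sum(n * a))
}

# orient face so its normal points away from `interior`
orient_face <- function(pts, f, interior) {
  pl <- face_plane(pts, f)
  if (is.null(pl)) return(f)
  if (sum(pl$n * interior) - pl$d > 0) f[c(2, 3)] <- f[c(3, 2)]
  f
}

#' Convex hull of a 3D point set
#'
#' Quickhull with a tolerance scaled to the point cloud extent. Degenerate
#' inputs (fewer than 4 points, or collinear/coplanar sets) return zero volume
#' with `degenerate = TRUE`.
#'
#' @param pts numeric `n x 3` matrix of points.
#' @return list with `vertices` (row indices of hull vertices), `faces`
#'   (`k x 3` matrix of outward-oriented vertex triples, `NULL` when
#'   degenerate), `volume`, and `degenerate` flag.
#' @export
convex_hull_3d <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 3L)
  n <- nrow(pts)
  degenerate <- function() list(vertices = seq_len(n), faces = NULL,
                                volume = 0, degenerate = TRUE)
  if (n < 4L) return(degenerate())
  extent <- max(apply(pts, 2, function(x) diff(range(x))), 0)
  if (extent <= 0) return(degenerate())
  eps <- 1e-9 * extent

  # initial simplex from axis extremes
  ext <- unique(c(apply(pts, 2, which.min), apply(pts, 2, which.max)))
  if (length(ext) < 2L) return(degenerate())
  dd <- as.matrix(stats::dist(pts[ext, , drop = FALSE]))
  ij <- which(dd == max(dd), arr.ind = TRUE)[1L, ]
  i1 <- ext[ij[1]]; i2 <- ext[ij[2]]
  if (dd[ij[1], ij[2]] < eps) return(degenerate())
  u <- pts[i2, ] - pts[i1, ]
  rel <- sweep(pts, 2, pts[i1, ])
  proj <- (rel %*% u) / sum(u^2)
  perp <- rel - proj %*% t(u)
  dline <- sqrt(rowSums(perp^2))
  i3 <- which.max(dline)
  if (dline[i3] < eps) return(degenerate()) # collinear
  nrm <- cross3(u, pts[i3, ] - pts[i1, ])
  nrm <- nrm / sqrt(sum(nrm^2))
  dplane <- as.numeric(rel %*% nrm)
  i4 <- which.max(abs(dplane))
  if (abs(dplane[i4]) < eps) return(degenerate()) # coplanar
  interior <- colMeans(pts[c(i1, i2, i3, i4), ])

  faces <- list(orient_face(pts, c(i1, i2, i3), interior),
                orient_face(pts, c(i1, i2, i4), interior),
                orient_face(pts, c(i1, i3, i4), interior),
                orient_face(pts, c(i2, i3, i4), interior))
  alive <- rep(TRUE, 4L)
  planes <- lapply(faces, function(f) face_plane(pts, f))
  outside <- vector("list", 4L)
  unassigned <- setdiff(seq_len(n), c(i1, i2, i3, i4))
  for (fi in seq_along(faces)) {
    if (!length(unassigned)) break
    sd <- pts[unassigned, , drop = FALSE] %*% planes[[fi]]$n - planes[[fi]]$d
    far <- sd > eps
    outside[[fi]] <- unassigned[far]
    unassigned <- unassigned[!far]
  }

  repeat {
    fi <- which(alive & vapply(outside, length, integer(1)) > 0L)
    if (!length(fi)) break
    fi <- fi[1L]
    pl <- planes[[fi]]
    cand <- outside[[fi]]
    sd <- pts[cand, , drop = FALSE] %*% pl$n - pl$d
    p <- cand[which.max(sd)]
    # faces visible from p
    vis <- which(alive & vapply(seq_along(faces), function(k) {
      if (!alive[k]) return(FALSE)
      sum(planes[[k]]$n * pts[p, ]) - planes[[k]]$d > eps
    }, logical(1)))
    # horizon: directed edges of visible faces whose reverse is not visible
    edges <- do.call(rbind, lapply(vis, function(k) {
      f <- faces[[k]]
      rbind(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])
    }))
    keys <- paste(edges[, 1], edges[, 2])
    rev_keys <- paste(edges[, 2], edges[, 1])
    horizon <- edges[!(rev_keys %in% keys), , drop = FALSE]
    pool <- unique(unlist(outside[vis]))
    pool <- setdiff(pool, p)
    alive[vis] <- FALSE
    for (k in vis) outside[[k]] <- integer(0)
    for (e in seq_len(nrow(horizon))) {
      f <- orient_face(pts, c(horizon[e, 1], horizon[e, 2], p), interior)
      pl2 <- face_plane(pts, f)
      if (is.null(pl2)) next
      faces[[length(faces) + 1L]] <- f
      planes[[length(planes) + 1L]] <- pl2
      alive[length(faces)] <- TRUE
      if (length(pool)) {
        sd2 <- pts[pool, , drop = FALSE] %*% pl2$n - pl2$d
        far <- sd2 > eps
        outside[[length(faces)]] <- pool[far]
        pool <- pool[!far]
      } else {
        outside[[length(faces)]] <- integer(0)
      }
    }
  }

  fmat <- do.call(rbind, faces[alive])
  verts <- sort(unique(as.vector(fmat)))
  vol <- 0
  for (k in seq_len(nrow(fmat))) {
    a <- pts[fmat[k, 1], ] - interior
    b <- pts[fmat[k, 2], ] - interior
    cc <- pts[fmat[k, 3], ] - interior
    vol <- vol + sum(a * cross3(b, cc)) / 6
  }
  list(vertices = verts, faces = fmat, volume = abs(vol), degenerate = FALSE)
}

#' Maximum pairwise distance of a point set (maximum caliper)
#'
#' Computed over convex-hull vertices (exact, since the diameter of a point
#' set is attained at hull vertices); falls back to all points for degenerate
#' hulls.
#'
#' @param pts numeric `n x 3` matrix.
#' @return largest Euclidean distance between any two points.
#' @export
max_caliper <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(0)
  h <- convex_hull_3d(pts)
  cand <- if (h$degenerate) pts else pts[h$vertices, , drop = FALSE]
  max_pairwise_dist(cand)
}

# chunked all-pairs maximum distance (also the brute-force Feret oracle)
max_pairwise_dist <- function(pts, chunk = 2000L) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  sq <- rowSums(pts^2)
  best <- 0
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    g <- pts[i0:i1, , drop = FALSE]
    d2 <- outer(sq[i0:i1], sq, "+") - 2 * g %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
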