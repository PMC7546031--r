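mask_at <- function(center_um, r = 1.5, dims = c(16, 80, 80),
                    spacing = SP_DEFAULT) {
  ax <- lapply(1:3, function(a) (seq_len(dims[a]) - 0.5) * spacing[a])
  q <- outer(outer((ax[[1]] - center_um[1])^2, (ax[[2]] - center_um[2])^2, "+"),
             (ax[[3]] - center_um[3])^2, "+")
  cell_mask(array(q <= r^2, dims), spacing)
}

test_that("binary centroids hit digitized sphere centres", {
  m <- mask_at(c(8, 10, 10), r = 2.5)
  ctr <- isletmorph:::mask_centroid(m$mask, SP_DEFAULT)
  expect_true(all(abs(ctr - c(8, 10, 10)) <= SP_DEFAULT / 2))
  # translation by whole voxels moves the centroid by exactly that offset
  m2 <- cell_mask(isletmorph:::shift_array3d(m$mask, c(2, 10, -5), fill = FALSE),
                  SP_DEFAULT)
  ctr2 <- isletmorph:::mask_centroid(m2$mask, SP_DEFAULT)
  expect_equal(ctr2 - ctr, c(2, 10, -5) * SP_DEFAULT, tolerance = 1e-9)
})

test_that("centres of a rendered 8-cell scene match the truth ledger", {
  centers <- rbind(
    c(7, 8, 8), c(7, 8, 20), c(7, 20, 8), c(7, 20, 20),
    c(13, 8, 8), c(13, 8, 20), c(13, 20, 8), c(13, 20, 20))
  cells <- lapply(seq_len(8), function(i) {
    cell_spec(center = centers[i, ], semi_axes = rep(2, 3))
  })
  spec <- scene_spec(grid_shape = c(20, 94, 94), cells = cells,
                     noise = noise_spec(0, 0, 0), psf_sigma = c(0, 0, 0),
                     seed = 51)
  sc <- render_scene(spec)
  v <- get_frame(sc$image)
  lab <- isletmorph:::label_components(v > 50, 26L)
  masks <- lapply(1:8, function(i) NULL)
  got <- matrix(NA_real_, 8, 3)
  for (l in seq_len(max(lab))) {
    ctr <- isletmorph:::mask_centroid(lab == l, spec$voxel_spacing)
    i <- which.min(colSums((t(centers) - ctr)^2))
    got[i, ] <- ctr
  }
  expect_true(all(abs(got - centers) <= rep(spec$voxel_spacing, each = 8)))
})

test_that("extract_centers flags absences and rejects empty present masks", {
  tracks <- extract_centers(list(
    a = list(mask_at(c(8, 10, 10)), NULL),
    b = list(mask_at(c(8, 14, 10)), mask_at(c(8, 13, 10)))))
  expect_equal(nrow(tracks), 4L)
  expect_false(tracks$present[tracks$cell_id == "a" & tracks$frame == 2])
  expect_true(is.na(tracks$z[2]))
})

test_that("normalization places the reference at the origin and is rigid", {
  tracks <- extract_centers(list(
    ref = list(mask_at(c(8, 10, 10)), mask_at(c(8, 12, 10))),
    b = list(mask_at(c(8, 14, 10)), mask_at(c(8, 14, 12)))))
  nt <- normalize_to_reference(tracks, "ref")
  expect_true(all(abs(nt[nt$cell_id == "ref", c("z", "y", "x")]) < 1e-9))
  # adding a rigid whole-field translation changes nothing after normalization
  shifted <- tracks
  shifted[, c("z", "y", "x")] <- shifted[, c("z", "y", "x")] + rep(c(1, 2, 3), each = 4)
  nt2 <- normalize_to_reference(shifted, "ref")
  expect_equal(nt2[, c("z", "y", "x")], nt[, c("z", "y", "x")], tolerance = 1e-9)
  # reference must exist at every frame
  tracks$present[tracks$cell_id == "ref" & tracks$frame == 2] <- FALSE
  expect_error(normalize_to_reference(tracks, "ref"), "absent")
  expect_error(normalize_to_reference(tracks, "ghost"), "not found")
})

test_that("distance series are symmetric and summarize trends", {
  mk <- function(cells) do.call(rbind, lapply(names(cells), function(cn) {
    m <- cells[[cn]]
    data.frame(cell_id = cn, frame = seq_len(nrow(m)), present = TRUE,
               z = m[, 1], y = m[, 2], x = m[, 3])
  }))
  static <- mk(list(a = cbind(5, 5, 5)[rep(1, 4), ],
                    b = cbind(5, 17, 5)[rep(1, 4), ]))
  ds <- distance_series(static, c("a", "b"))
  expect_equal(ds$series$distance_um, rep(12, 4))
  expect_equal(ds$delta, 0)
  # scripted approach 15 -> 5 um over 10 frames
  appr <- mk(list(a = cbind(5, 5, 5)[rep(1, 10), ],
                  b = cbind(5, 5 + seq(15, 5, length.out = 10), 5)))
  da <- distance_series(appr, c("a", "b"))
  expect_equal(da$delta, -10, tolerance = 1e-9)
  expect_equal(da$tau, -1)
  expect_identical(distance_series(appr, c("b", "a"))$series, da$series)
  expect_error(distance_series(static[static$frame == 1, ], c("a", "b")),
               "common frames")
})

test_that("distances are invariant to reference normalization", {
  tracks <- extract_centers(list(
    ref = list(mask_at(c(8, 10, 10)), mask_at(c(8, 12, 10))),
    b = list(mask_at(c(8, 14, 10)), mask_at(c(8, 14, 12)))))
  d_raw <- distance_series(tracks, c("ref", "b"))$series$distance_um
  d_norm <- distance_series(normalize_to_reference(tracks, "ref"),
                            c("ref", "b"))$series$distance_um
  expect_equal(d_raw, d_norm, tolerance = 1e-9)
})

test_that("hull volume of cube-corner centres is exact and degeneracy flagged", {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1)) + 5
  tracks <- data.frame(cell_id = paste0("c", 1:8), frame = 1, present = TRUE,
                       z = corners[, 1], y = corners[, 2], x = corners[, 3])
  hm <- hull_metric(tracks, 1)
  expect_equal(hm$hull_volume_um3, 1)
  expect_equal(hm$n_cells, 8L)
  expect_false(hm$degenerate)
  col <- data.frame(cell_id = paste0("c", 1:5), frame = 1, present = TRUE,
                    z = 1:5, y = 2 * (1:5), x = 3 * (1:5))
  hc <- hull_metric(col, 1)
  expect_equal(hc$hull_volume_um3, 0)
  expect_true(hc$degenerate)
})

test_that("a scripted coalescing cluster shrinks in hull volume and distances", {
  n_frames <- 6
  base <- rbind(c(8, 10, 10), c(8, 22, 10), c(8, 10, 22), c(8, 22, 22),
                c(12, 16, 16))
  target <- c(10, 16, 16)
  rows <- list()
  for (i in seq_len(nrow(base))) {
    for (t in seq_len(n_frames)) {
      p <- base[i, ] + (target - base[i, ]) * 0.12 * (t - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = paste0("c", i), frame = t, present = TRUE,
        z = p[1], y = p[2], x = p[3])
    }
  }
  tracks <- do.call(rbind, rows)
  hm <- hull_metric(tracks)
  expect_true(all(diff(hm$hull_volume_um3) < 0))
  d <- distance_series(tracks, c("c1", "c4"))
  expect_true(all(diff(d$series$distance_um) < 0))
  expect_equal(d$tau, -1)
})
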