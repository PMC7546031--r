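# Tracing accuracy on rendered scenes is noise-free here (the stochastic
# cohort recovery lives with the acceptance checks); these tests pin the
# per-operation contracts.

one_cell_scene <- function(filos, seed, noise = noise_spec(0, 0, 0)) {
  cell <- cell_spec(center = c(12, 18, 18), semi_axes = rep(3.5, 3),
                    filopodia = filos)
  scene_spec(grid_shape = c(24, 120, 120), cells = list(cell),
             noise = noise, seed = seed)
}

test_that("a straight 6-um filopodium traces to within 15%", {
  spec <- one_cell_scene(list(filopodium_spec(c(0, 1, 0), 6)), seed = 41)
  sc <- render_scene(spec)
  body <- purify(hysteresis_segment(sc$image))
  tr <- trace_filopodia(sc$image, body)
  expect_length(tr, 1L)
  expect_lt(abs(tr[[1]]$length - 6) / 6, 0.15)
  expect_gte(nrow(tr[[1]]$path), 2L)
  # polyline length equals the reported geodesic length (minus the margin)
  seg <- diff(tr[[1]]$path)
  poly <- sum(sqrt(rowSums(seg^2)))
  expect_equal(poly + dynamics_params()$body_margin, tr[[1]]$length,
               tolerance = 1e-9)
})

test_that("a bare sphere yields no traces", {
  spec <- one_cell_scene(list(), seed = 42)
  sc <- render_scene(spec)
  body <- purify(hysteresis_segment(sc$image))
  expect_length(trace_filopodia(sc$image, body), 0L)
})

test_that("three filopodia are recovered in the correct length order", {
  spec <- one_cell_scene(list(
    filopodium_spec(c(0, 1, 0), 9),
    filopodium_spec(c(0, 0, 1), 5),
    filopodium_spec(c(0, -0.7, 0.7), 2)), seed = 43)
  sc <- render_scene(spec)
  body <- purify(hysteresis_segment(sc$image))
  tr <- trace_filopodia(sc$image, body)
  expect_length(tr, 3L)
  lens <- sapply(tr, `[[`, "length")
  # base directions identify the filopodia; order must match 9 > 5 > 2
  dirs <- t(sapply(tr, function(t) {
    d <- t$base_point - c(12, 18, 18)
    d / sqrt(sum(d^2))
  }))
  truth_dir <- rbind(c(0, 1, 0), c(0, 0, 1), c(0, -0.7, 0.7) / sqrt(0.98))
  assign <- apply(dirs %*% t(truth_dir), 1, which.max)
  expect_setequal(assign, 1:3)
  expect_equal(order(lens[order(assign)], decreasing = TRUE), 1:3)
})

test_that("tracks persist, stay separated, and open on scripted appearance", {
  n_frames <- 11
  stable <- filopodium_spec(c(0, 1, 0), rep(4, n_frames))
  far <- filopodium_spec(c(0, -1, 0), rep(3, n_frames)) # base 7 um away
  appearing <- filopodium_spec(c(0, 0, 1), c(rep(0, 4), rep(3.5, 7)))
  cell <- cell_spec(center = c(12, 18, 18), semi_axes = rep(3.5, 3),
                    filopodia = list(stable, far, appearing))
  spec <- scene_spec(grid_shape = c(24, 120, 120), cells = list(cell),
                     noise = noise_spec(0, 0, 0), n_frames = n_frames,
                     seed = 44)
  sc <- render_scene(spec)
  tracks <- analyze_filopodia_series(sc$image)
  expect_length(tracks, 3L)
  n_pres <- sapply(tracks, function(tk) length(tk$frames))
  first_frame <- sapply(tracks, function(tk) min(tk$frames))
  expect_setequal(n_pres, c(11, 11, 7))
  expect_equal(first_frame[which(n_pres == 7)], 5)
  # the two persistent tracks never merge: base points stay ~7 um apart
  b <- t(sapply(tracks[n_pres == 11], function(tk) colMeans(tk$base_points)))
  expect_gt(sqrt(sum((b[1, ] - b[2, ])^2)), 5)
})

test_that("linking matches nearest bases within the gate only", {
  tr_at <- function(base, len) list(path = rbind(base, base + c(0, len, 0)),
                                    length = len, base_point = base,
                                    tip_point = base + c(0, len, 0),
                                    component = 1L)
  f1 <- list(tr_at(c(5, 5, 5), 3), tr_at(c(5, 15, 5), 4))
  f2 <- list(tr_at(c(5, 15.5, 5), 4.2), tr_at(c(5, 5.4, 5), 3.1))
  tracks <- link_tracks(list(f1, f2), dynamics_params())
  expect_length(tracks, 2L)
  expect_equal(sapply(tracks, function(tk) length(tk$frames)), c(2, 2))
  # a trace beyond the gate opens a new track instead
  f3 <- list(tr_at(c(5, 25, 5), 3))
  tracks3 <- link_tracks(list(f1, f3), dynamics_params())
  expect_length(tracks3, 3L)
})

test_that("classification window must fit the series", {
  track <- list(track_id = 1L, frames = 1:5, lengths = rep(2, 5),
                base_points = matrix(0, 5, 3))
  expect_error(classify_dynamics(track, dynamics_params(), n_frames = 5),
               "window")
  short <- classify_dynamics(track,
                             dynamics_params(series_duration = 8), n_frames = 5)
  expect_equal(short$dynamic_events, 0L)
  expect_true(short$stable)
})

test_that("raising min_length never increases the number of tracked filopodia", {
  spec <- one_cell_scene(list(
    filopodium_spec(c(0, 1, 0), 8),
    filopodium_spec(c(0, 0, 1), 3),
    filopodium_spec(c(0, -1, 0), 2)), seed = 45, noise = noise_spec())
  sc <- render_scene(spec)
  img <- preprocess(sc$image)
  counts <- sapply(c(1, 2.5, 4, 9), function(ml) {
    body <- purify(hysteresis_segment(img))
    tr <- trace_filopodia(img, body)
    sum(sapply(tr, `[[`, "length") >= ml)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("per-cell summaries compare groups and handle empty cells", {
  mk_track <- function(lengths) {
    pres <- which(lengths > 0)
    list(track_id = 1L, frames = pres, lengths = lengths[pres],
         base_points = matrix(0, length(pres), 3))
  }
  stable_tracks <- list(mk_track(rep(3, 11)), mk_track(rep(4, 11)))
  dynamic_tracks <- list(mk_track(c(rep(0, 5), rep(3, 6))),
                         mk_track(c(rep(3, 6), rep(0, 5))))
  cohort <- c(lapply(1:10, function(i) stable_tracks),
              lapply(1:10, function(i) dynamic_tracks))
  names(cohort) <- paste0("c", 1:20)
  groups <- setNames(rep(c("clustered", "isolated"), each = 10), names(cohort))
  # idealized cohorts have zero within-group variance; the t-test warns
  s <- suppressWarnings(summarize_dynamics(cohort, groups, n_frames = 11))
  expect_equal(nrow(s$per_cell), 20L)
  st <- s$tests[s$tests$field == "stable_filopodia", ]
  expect_lt(st$p_value, 0.05)
  # identical cohorts: p = 1 for both summaries
  cohort2 <- c(lapply(1:4, function(i) stable_tracks),
               lapply(1:4, function(i) stable_tracks))
  names(cohort2) <- paste0("c", 1:8)
  groups2 <- setNames(rep(c("a", "b"), each = 4), names(cohort2))
  suppressWarnings(s2 <- summarize_dynamics(cohort2, groups2, n_frames = 11))
  expect_true(all(s2$tests$p_value == 1))
  # a cell with no tracks contributes zero counts
  cohort3 <- list(c1 = stable_tracks, c2 = list())
  s3 <- summarize_dynamics(cohort3, c(c1 = "a", c2 = "b"), n_frames = 11)
  expect_equal(s3$per_cell$dynamic_events[2], 0L)
  expect_equal(s3$per_cell$stable_filopodia[2], 0L)
})

test_that("traces tabulate tidily", {
  spec <- one_cell_scene(list(filopodium_spec(c(0, 1, 0), 5)), seed = 46)
  sc <- render_scene(spec)
  body <- purify(hysteresis_segment(sc$image))
  df <- traces_to_df(list(trace_filopodia(sc$image, body)))
  expect_named(df, c("frame", "trace", "length_um", "base_z", "base_y", "base_x"))
  expect_equal(nrow(df), 1L)
  expect_equal(nrow(traces_to_df(list(list()))), 0L)
})
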