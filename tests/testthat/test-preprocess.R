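test_that("a constant image preprocesses to zeros", {
  img <- vol_image(array(7, c(6, 20, 20)), c(1, 0.3, 0.3))
  out <- preprocess(img, median_radius = 1, bg_radius = 2)
  expect_true(all(out$data == 0))
})

test_that("the median filter removes an isolated bright voxel", {
  a <- array(0, c(6, 20, 20))
  a[3, 10, 10] <- 100
  img <- vol_image(a, c(1, 0.3, 0.3))
  out <- preprocess(img, median_radius = 1, bg_radius = 0,
                    clip_percentiles = c(0, 100))
  expect_equal(max(out$data), 0)
})

test_that("preprocessing reduces background variance on a noisy scene", {
  spec <- sphere_scene(r = 3, seed = 8, noise = noise_spec(),
                       psf = c(0.6, 0.25, 0.25))
  sc <- render_scene(spec)
  out <- preprocess(sc$image, clip_percentiles = c(0, 100))
  v_in <- get_frame(sc$image)
  v_out <- get_frame(out)
  bg <- v_in < otsu_threshold(v_in) / 4 # far background region
  # compare on a common scale: normalize both to their own max
  expect_lt(stats::var(v_out[bg] / max(v_out)), stats::var(v_in[bg] / max(v_in)))
})

test_that("preprocess is deterministic and validates its arguments", {
  spec <- sphere_scene(r = 2, seed = 9, noise = noise_spec())
  sc <- render_scene(spec)
  expect_identical(preprocess(sc$image)$data, preprocess(sc$image)$data)
  expect_error(preprocess(sc$image, clip_percentiles = c(99, 1)), "increasing")
  expect_error(preprocess(sc$image, median_radius = -1), ">= 0")
})

test_that("known drifts are recovered within one voxel per axis", {
  # steps up to 5 voxels/frame over a 10-frame series
  for (drift_um in list(c(0, 1.2, 0), c(0, 0.9, -1.2), c(1, 1.5, 0.6))) {
    spec <- sphere_scene(r = 3, seed = 10, noise = noise_spec(),
                         psf = c(0.6, 0.25, 0.25), n_frames = 10,
                         drift = drift_um)
    sc <- render_scene(spec)
    res <- correct_drift(sc$image)
    true_vox <- t(sapply(1:10, function(t) {
      (t - 1) * drift_um / spec$voxel_spacing
    }))
    got <- as.matrix(res$drift[, c("dz", "dy", "dx")])
    expect_true(all(abs(got - true_vox) <= 1),
                label = paste("drift", paste(drift_um, collapse = ",")))
  }
})

test_that("a static duplicated frame registers with zero shift", {
  spec <- sphere_scene(r = 3, seed = 11, noise = noise_spec(0, 0, 0),
                       psf = c(0.6, 0.25, 0.25))
  sc <- render_scene(spec)
  v <- get_frame(sc$image)
  img <- vol_image(array(rep(v, 2), c(2, 1, dim(v))[c(1, 2, 3, 4, 5)]),
                   sc$image$voxel_spacing)
  img$data[1, 1, , , ] <- v
  img$data[2, 1, , , ] <- v
  res <- correct_drift(img)
  expect_equal(unlist(res$drift[2, c("dz", "dy", "dx")]), c(dz = 0, dy = 0, dx = 0))
})

test_that("drift estimated on the reference channel applies to all channels", {
  spec <- sphere_scene(r = 3, seed = 12, noise = noise_spec(0, 0, 0),
                       psf = c(0.6, 0.25, 0.25), n_frames = 3,
                       drift = c(0, 1.2, 0))
  spec$n_channels <- 2L
  spec$cells[[1]]$channel_intensity <- c(1, 0.6)
  sc <- render_scene(spec)
  r1 <- correct_drift(sc$image, reference_channel = 1)
  r2 <- correct_drift(sc$image, reference_channel = 2)
  expect_identical(r1$drift, r2$drift)
  # the registered peak of every corrected frame sits at the frame-1 peak
  for (t in 2:3) {
    p0 <- arrayInd(which.max(get_frame(r1$image, 1, 2)), dim(get_frame(r1$image, 1, 2)))
    pt <- arrayInd(which.max(get_frame(r1$image, t, 2)), dim(get_frame(r1$image, 1, 2)))
    expect_true(all(abs(p0 - pt) <= 1))
  }
})

test_that("an all-zero frame is reported by name", {
  spec <- sphere_scene(r = 3, seed = 13, n_frames = 2)
  sc <- render_scene(spec)
  sc$image$data[2, 1, , , ] <- 0
  expect_error(correct_drift(sc$image), "frame 2")
})

test_that("frame and slice exclusion obeys its contract", {
  spec <- sphere_scene(r = 3, seed = 14, n_frames = 3)
  sc <- render_scene(spec)
  expect_identical(exclude_frames(sc$image, integer(0)), sc$image)
  nz <- dim(sc$image$data)[3]
  out <- exclude_frames(sc$image, 2L, axis = "z")
  expect_equal(dim(out$data)[3], nz - 1L)
  expect_identical(out$data[1, 1, 2, , ], sc$image$data[1, 1, 3, , ])
  expect_error(exclude_frames(sc$image, c(1, 1), axis = "z"), "duplicate")
  expect_error(exclude_frames(sc$image, seq_len(nz), axis = "z"), "every")
  expect_error(exclude_frames(sc$image, 99L, axis = "t"), "range")
  expect_match(out$log[[length(out$log)]]$step, "exclude")
})
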