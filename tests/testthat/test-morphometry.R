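test_that("a digitized 5-um sphere measures like the analytic sphere", {
  m <- sphere_mask(5)
  cm <- measure_cell(m)
  expect_lt(abs(cm$volume_um3 - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
  expect_gte(cm$sphericity, 0.97)
  expect_lte(cm$sphericity, 1.02)
  expect_lt(abs(cm$feret_um - 10) / 10, 0.05)
  # caliper >= equivalent-sphere diameter, up to voxelization of each
  expect_gt(cm$feret_um, 2 * (3 * cm$volume_um3 / (4 * pi))^(1 / 3) * 0.99)
})

test_that("measurements obey isotropic scaling laws", {
  a <- measure_cell(sphere_mask(2.5))
  b <- measure_cell(sphere_mask(5))
  expect_lt(abs(b$volume_um3 / a$volume_um3 - 8) / 8, 0.02)
  expect_lt(abs(b$surface_area_um2 / a$surface_area_um2 - 4) / 4, 0.02)
  expect_lt(abs(b$sphericity - a$sphericity), 0.01)
})

test_that("a 2:1:1 ellipsoid is its own best-fit ellipsoid", {
  m <- cell_mask(digitize_ellipsoid(c(4, 8, 4), pad = 2), SP_DEFAULT)
  cm <- measure_cell(m)
  expect_lt(abs(cm$volume_ellipsoid_ratio - 1), 0.05)
  sphere <- measure_cell(sphere_mask(4))
  expect_lt(cm$sphericity, sphere$sphericity)
})

test_that("sphericity is invariant under rigid translation", {
  base <- digitize_sphere(3.5, pad = 5)
  moved <- isletmorph:::shift_array3d(base, c(2, 5, -4), fill = FALSE)
  a <- measure_cell(cell_mask(base, SP_DEFAULT))
  b <- measure_cell(cell_mask(moved, SP_DEFAULT))
  expect_lt(abs(a$sphericity - b$sphericity), 0.01)
  expect_equal(a$volume_um3, b$volume_um3)
})

test_that("voxel-count volume agrees with mesh-enclosed volume", {
  for (r in c(2, 3, 5)) { # >= 4 um diameter
    cm <- measure_cell(sphere_mask(r))
    expect_lt(abs(cm$mesh_volume_um3 - cm$volume_um3) / cm$volume_um3, 0.03)
  }
})

test_that("convex masks have volume:ellipsoid ratio at most ~1", {
  for (semi in list(c(3, 3, 3), c(4, 6, 3), c(2.5, 5, 5))) {
    cm <- measure_cell(cell_mask(digitize_ellipsoid(semi, pad = 2), SP_DEFAULT))
    expect_lte(cm$volume_ellipsoid_ratio, 1.05)
  }
})

test_that("hull-based Feret equals the brute-force all-pairs maximum", {
  for (s in 1:5) {
    m <- random_blob_mask(s)
    pts <- isletmorph:::surface_points(m, SP_DEFAULT)
    expect_equal(max_caliper(pts), isletmorph:::max_pairwise_dist(pts),
                 tolerance = 1e-12)
  }
})

test_that("too-thin masks raise a meshing error with guidance", {
  a <- array(FALSE, c(6, 12, 12))
  a[3, 2:10, 2:10] <- TRUE # single z-plane slab
  expect_error(measure_cell(cell_mask(a, SP_DEFAULT)), "thinner")
})

test_that("the two-group t-test matches the closed form", {
  d <- data.frame(v = c(1, 2, 3, 4, 5, 6), group = rep(c("a", "b"), each = 3))
  tt <- compare_groups(d, "v")
  expect_equal(tt$t, -3 * sqrt(3 / 2), tolerance = 1e-6) # = -3.674
  expect_equal(tt$df, 4)
  expect_equal(tt$p_value, 2 * stats::pt(-3 * sqrt(3 / 2), 4), tolerance = 1e-9)
  # identical groups: p = 1, t = 0
  d2 <- data.frame(v = rep(c(1, 2, 3), 2), group = rep(c("a", "b"), each = 3))
  tt2 <- compare_groups(d2, "v")
  expect_equal(tt2$t, 0)
  expect_equal(tt2$p_value, 1)
  # permutation of rows within groups changes nothing
  d3 <- d[c(3, 1, 2, 6, 5, 4), ]
  expect_equal(compare_groups(d3, "v"), tt)
  # zero-variance groups warn but report
  d4 <- data.frame(v = c(1, 1, 2, 2), group = c("a", "a", "b", "b"))
  expect_warning(tt4 <- compare_groups(d4, "v"), "zero variance")
  expect_equal(tt4$p_value, 0)
  # Welch flag switches the method
  expect_match(compare_groups(d, "v", welch = TRUE)$method, "welch")
})

test_that("regression handles collinear, constant and degenerate inputs", {
  d <- data.frame(x = 1:5, y = 2 * (1:5) + 1)
  r <- regress_fields(d, "x", "y")
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 2)
  d2 <- data.frame(x = 1:5, y = rep(3, 5))
  r2 <- regress_fields(d2, "x", "y")
  expect_equal(r2$r_squared, 0)
  expect_equal(r2$slope, 0)
  expect_error(regress_fields(data.frame(x = rep(1, 5), y = 1:5), "x", "y"),
               "variance")
  expect_error(regress_fields(data.frame(x = 1:2, y = 1:2), "x", "y"), "fewer")
})

test_that("an imposed linear trend across groups is recovered", {
  withr::with_seed(21, {
    sph <- stats::runif(24, 0.5, 0.95)
    ratio <- 0.8 * sph + 0.1 + stats::rnorm(24, 0, 0.01)
    d <- data.frame(sphericity = sph, volume_ellipsoid_ratio = ratio,
                    group = rep(c("isolated", "clustered"), each = 12))
    r <- regress_fields(d, "sphericity", "volume_ellipsoid_ratio", "group")
    expect_equal(nrow(r), 2L)
    expect_true(all(abs(r$slope - 0.8) / 0.8 < 0.1))
    expect_true(all(r$r_squared > 0.9))
  })
})
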