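test_that("sphere phantom carries exact analytic truth and honours its preconditions", {
  ph <- make_sphere_phantom(20, 0.5)
  expect_equal(ph$truth$analytic_S_mm2, 4 * pi * 400, tolerance = 1e-12)
  expect_equal(ph$truth$analytic_V_mm3, 4 / 3 * pi * 8000, tolerance = 1e-12)
  expect_equal(ph$truth$analytic_hii, 100, tolerance = 1e-10)
  expect_error(make_sphere_phantom(3, 1), class = "hii_resolution_error")
  expect_error(make_sphere_phantom(20, 1, hu_foreground = 120),
               class = "hii_domain_error")
  expect_error(make_sphere_phantom(20, 1, hu_background = 50),
               class = "hii_domain_error")
})

test_that("phantom noise is seeded and deterministic", {
  a <- make_sphere_phantom(8, 1, noise_sd = 5, seed = 42)
  b <- make_sphere_phantom(8, 1, noise_sd = 5, seed = 42)
  expect_identical(a$volume$voxels, b$volume$voxels)
  c <- make_sphere_phantom(8, 1, noise_sd = 5, seed = 43)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
  # noise off: seed irrelevant
  d1 <- make_sphere_phantom(8, 1, seed = 1)
  d2 <- make_sphere_phantom(8, 1, seed = 2)
  expect_identical(d1$volume$voxels, d2$volume$voxels)
})

test_that("phantom generation does not disturb the global RNG stream", {
  set.seed(123); before <- .Random.seed
  invisible(make_sphere_phantom(8, 1, noise_sd = 5, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("ellipsoid truth: sphere reduction and prolate closed form", {
  ph <- make_ellipsoid_phantom(15, 15, 15, 0.5)
  expect_equal(ph$truth$analytic_hii, 100, tolerance = 1e-10)
  expect_equal(ph$truth$analytic_S_mm2, 4 * pi * 225, tolerance = 1e-9)

  # independent evaluation of the prolate closed form
  a <- 20; b <- 10; e <- sqrt(1 - b^2 / a^2)
  S <- 2 * pi * b^2 * (1 + (a / (b * e)) * asin(e))
  ph <- make_ellipsoid_phantom(a, b, b, 0.5)
  expect_equal(ph$truth$analytic_S_mm2, S, tolerance = 1e-12)
  expect_equal(ph$truth$analytic_hii, 103.766, tolerance = 1e-3)
  ph4 <- make_ellipsoid_phantom(40, 10, 10, 0.5)
  expect_equal(ph4$truth$analytic_hii, 113.090, tolerance = 1e-3)
  expect_gt(ph4$truth$analytic_hii, ph$truth$analytic_hii)
})

test_that("triaxial numeric integration matches the spheroid closed forms", {
  # nudge one semi-axis so the triaxial integration path is taken, then
  # compare against the exact spheroid areas
  tri <- hii:::.ellipsoid_area(20, 10, 10 + 1e-6)
  expect_match(tri$note, "integration")
  prolate <- hii:::.ellipsoid_area(20, 10, 10)
  expect_match(prolate$note, "prolate")
  expect_equal(tri$S, prolate$S, tolerance = 1e-6)

  tri_ob <- hii:::.ellipsoid_area(10, 20, 20 + 1e-6)
  oblate <- hii:::.ellipsoid_area(10, 20, 20)
  expect_match(oblate$note, "oblate")
  expect_equal(tri_ob$S, oblate$S, tolerance = 1e-6)
})

test_that("lobulated phantom is deterministic, connected, and reduces to a sphere", {
  a <- make_lobulated_phantom(5, seed = 9, refine = 0)
  b <- make_lobulated_phantom(5, seed = 9, refine = 0)
  expect_identical(a$volume$voxels, b$volume$voxels)

  one <- make_lobulated_phantom(1, c(10, 10), 0, spacing_mm = 1, seed = 1,
                                refine = 0)
  met <- compute_hii_for_mask(segment_hematoma(one$volume))
  expect_lt(abs(met$hii - 100), 1)

  # the segmented union is a single 26-connected component by construction
  mask <- segment_hematoma(a$volume)
  expect_gt(sum(mask$voxels), 0)
})

test_that("lobulated shape is more irregular than an equal-volume sphere", {
  ph <- make_lobulated_phantom(5, seed = 7, refine = 0)
  met <- compute_hii_for_mask(segment_hematoma(ph$volume))
  r_eq <- (3 * met$volume_mm3 / (4 * pi))^(1 / 3)
  sphere <- make_sphere_phantom(r_eq, 1)
  met_s <- compute_hii_for_mask(segment_hematoma(sphere$volume))
  expect_gt(met$hii, met_s$hii)
})

test_that("brute-force lobulated oracle is self-consistent between refinements", {
  a4 <- make_lobulated_phantom(3, c(8, 10), 6, spacing_mm = 2, seed = 5,
                               refine = 4)
  a8 <- make_lobulated_phantom(3, c(8, 10), 6, spacing_mm = 2, seed = 5,
                               refine = 8)
  expect_equal(a4$truth$oracle_S_mm2, a8$truth$oracle_S_mm2, tolerance = 0.01)
  expect_equal(a4$truth$oracle_V_mm3, a8$truth$oracle_V_mm3, tolerance = 0.01)
})

test_that("thick-slice resampling: identity, volume recovery, degraded index", {
  ph <- make_sphere_phantom(20, 1)
  same <- resample_to_slices(ph$volume, 1)
  expect_identical(same$voxels, ph$volume$voxels)

  sliced <- resample_to_slices(ph$volume, 5)
  expect_equal(sliced$spacing_mm[1], 5)
  met5 <- compute_hii_for_mask(segment_hematoma(sliced))
  expect_equal(met5$volume_mm3, ph$truth$analytic_V_mm3, tolerance = 0.05)
  expect_gt(met5$hii, 95); expect_lt(met5$hii, 115)

  met1 <- compute_hii_for_mask(segment_hematoma(ph$volume))
  expect_gt(abs(met5$hii - 100), abs(met1$hii - 100))

  expect_error(resample_to_slices(sliced, 1), class = "hii_domain_error")
})

test_that("phantom_truth validates hii consistency with S and V", {
  expect_error(phantom_truth("bad", 4 * pi, 4 * pi / 3, analytic_hii = 110),
               class = "hii_domain_error")
  t <- phantom_truth("ok", 4 * pi, 4 * pi / 3)
  expect_equal(t$analytic_hii, 100, tolerance = 1e-10)
})
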