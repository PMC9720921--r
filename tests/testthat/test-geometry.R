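test_that("explicit unit-cube mesh has area 6 and volume 1", {
  cube <- unit_cube_mesh()
  expect_true(is_closed_mesh(cube))
  expect_equal(mesh_surface_area(cube), 6.0, tolerance = 1e-12)
  expect_equal(mesh_volume(cube), 1.0, tolerance = 1e-12)
  expect_identical(euler_characteristic(cube), 2L)
})

test_that("area and volume obey scaling and translation laws", {
  cube <- unit_cube_mesh()
  for (k in c(0.5, 2, 7)) {
    scaled <- triangle_mesh(cube$vertices * k, cube$faces)
    expect_equal(mesh_surface_area(scaled), 6 * k^2, tolerance = 1e-12)
    expect_equal(mesh_volume(scaled), k^3, tolerance = 1e-12)
  }
  moved <- triangle_mesh(sweep(cube$vertices, 2, c(100, 100, 100), "+"),
                         cube$faces)
  expect_equal(mesh_volume(moved), 1.0, tolerance = 1e-9)
  expect_equal(mesh_surface_area(moved), 6.0, tolerance = 1e-9)
})

test_that("single-voxel surface is closed with sub-voxel area and volume", {
  vox <- array(0L, dim = c(3, 3, 3)); vox[2, 2, 2] <- 1L
  mesh <- extract_surface(binary_mask(vox, c(1, 1, 1)))
  expect_true(is_closed_mesh(mesh))
  a <- mesh_surface_area(mesh); v <- mesh_volume(mesh)
  expect_gt(a, 0); expect_lt(a, 6)
  expect_gt(v, 0); expect_lt(v, 1)
  expect_identical(euler_characteristic(mesh), 2L)
})

test_that("sphere mask gives a closed genus-0 surface; torus gives genus 1", {
  mesh <- extract_surface(raster_sphere_mask(10, 0.5))
  expect_true(is_closed_mesh(mesh))
  expect_identical(euler_characteristic(mesh), 2L)

  sp <- 0.5; ax <- seq(-16, 16, by = sp); n <- length(ax)
  g <- expand.grid(x = ax, y = ax, z = ax)
  tor <- (sqrt(g$x^2 + g$y^2) - 10)^2 + g$z^2 <= 16
  tmesh <- extract_surface(binary_mask(array(tor, dim = c(n, n, n)),
                                       rep(sp, 3)))
  expect_true(is_closed_mesh(tmesh))
  expect_identical(euler_characteristic(tmesh), 0L)
})

test_that("anti-aliased sphere mesh converges to the analytic area and volume", {
  r <- 20
  errs <- sapply(c(2, 1, 0.5), function(sp) {
    mesh <- extract_surface(raster_sphere_mask(r, sp), antialias_sigma = 1.5)
    c(area = mesh_surface_area(mesh) / (4 * pi * r^2) - 1,
      vol = mesh_volume(mesh) / (4 / 3 * pi * r^3) - 1)
  })
  expect_lt(abs(errs["area", 3]), 0.03)
  expect_lt(abs(errs["vol", 3]), 0.01)
  # error decreases as the grid is refined
  expect_true(all(diff(abs(errs["area", ])) < 0))
  expect_true(all(diff(abs(errs["vol", ])) < 0))
})

test_that("mesh volume and voxel-count volume agree at fine spacing", {
  mask <- raster_sphere_mask(15, 0.5)
  mesh <- extract_surface(mask, antialias_sigma = 1.5)
  expect_equal(mesh_volume(mesh), voxel_volume(mask), tolerance = 0.02)
})

test_that("voxel_volume multiplies count by voxel size", {
  vox <- array(0L, dim = c(20, 20, 20)); vox[1:10, 1:10, 1:10] <- 1L
  m <- binary_mask(vox, c(5, 0.45, 0.45))
  expect_equal(voxel_volume(m), 1000 * 5 * 0.45 * 0.45, tolerance = 1e-12)
  expect_identical(voxel_volume(binary_mask(array(0L, c(2, 2, 2)),
                                            c(1, 1, 1))), 0)
})

test_that("open meshes are rejected by mesh_volume with the unmatched edge count", {
  cube <- unit_cube_mesh()
  open_mesh <- triangle_mesh(cube$vertices, cube$faces[-1, ])
  expect_false(is_closed_mesh(open_mesh))
  err <- expect_error(mesh_volume(open_mesh), class = "hii_format_error")
  expect_match(conditionMessage(err), "3 edges")
})

test_that("empty mask cannot be meshed", {
  expect_error(extract_surface(binary_mask(array(0L, c(3, 3, 3)), c(1, 1, 1))),
               class = "hii_domain_error")
})

test_that("Taubin smoothing: identity at 0 iterations, near-isometric on a sphere, corner-rounding on a cube", {
  mask <- raster_sphere_mask(15, 1)
  mesh <- extract_surface(mask, antialias_sigma = 1.5)
  expect_identical(smooth_mesh(mesh, 0), mesh)

  sm <- smooth_mesh(mesh, 20)
  expect_true(is_closed_mesh(sm))
  expect_identical(euler_characteristic(sm), euler_characteristic(mesh))
  expect_lt(abs(mesh_surface_area(sm) / mesh_surface_area(mesh) - 1), 0.02)

  cube <- binary_mask(array(1L, c(15, 15, 15)), c(1, 1, 1))
  cmesh <- extract_surface(cube)
  csm <- smooth_mesh(cmesh, 20)
  expect_lt(mesh_surface_area(csm), mesh_surface_area(cmesh))
})

test_that("every phantom mesh satisfies the isoperimetric inequality", {
  meshes <- list(
    extract_surface(raster_sphere_mask(10, 0.5), antialias_sigma = 1.5),
    extract_surface(segment_hematoma(
      make_ellipsoid_phantom(20, 10, 10, 0.5)$volume), antialias_sigma = 1.5),
    extract_surface(segment_hematoma(
      make_lobulated_phantom(3, c(5, 8), 5, 1, seed = 3,
                             refine = 0)$volume), antialias_sigma = 1.5))
  for (mesh in meshes) {
    s <- mesh_surface_area(mesh); v <- mesh_volume(mesh)
    expect_gte(s^3, 36 * pi * v^2 * (1 - 0.01))
  }
})

test_that("mesh export writes readable STL and PLY", {
  cube <- unit_cube_mesh()
  stl <- withr::local_tempfile(fileext = ".stl")
  ply <- withr::local_tempfile(fileext = ".ply")
  write_mesh(cube, stl); write_mesh(cube, ply)
  expect_identical(sum(grepl("^facet", readLines(stl))), 12L)
  ply_lines <- readLines(ply)
  expect_true("element vertex 8" %in% ply_lines)
  expect_true("element face 12" %in% ply_lines)
})
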