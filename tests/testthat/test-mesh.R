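test_that("isosurface area of a spherical pore matches 4*pi*r^2", {
  sp <- make_fixture("spherical_pore", n = 100, spacing = 0.01, radius = 0.3)
  path <- withr::local_tempfile(fileext = ".stl")
  tris <- export_surface(sp, path)
  expect_equal(mesh_area(tris), 4 * pi * 0.3^2, tolerance = 0.05)
})

test_that("degenerate grids refuse to produce a surface", {
  solid <- make_fixture("solid_block", n = 8, spacing = 0.1)
  expect_error(export_surface(solid, tempfile()), "solid")
  void <- voxel_grid(array(FALSE, dim = c(8, 8, 8)), 0.1)
  expect_error(export_surface(void, tempfile()), "void")
})

test_that("STL export round-trips through the binary reader", {
  g <- tpms_grid("gyroid", 0.3, 24)
  path <- withr::local_tempfile(fileext = ".stl")
  tris <- export_surface(g, path)
  expect_gt(nrow(tris), 0)
  back <- read_stl(path)
  expect_equal(nrow(back), nrow(tris))
  expect_equal(mesh_area(back), mesh_area(tris), tolerance = 1e-6)
  expect_true(all(is.finite(back)))
  # vertex coordinates live inside the physical grid extent
  expect_true(all(back >= -1e-6 & back <= 1 + 1e-6))
})
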