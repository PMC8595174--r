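test_that("channel skeleton tracks the axis and gives the channel diameter", {
  # odd grid: the channel axis passes through voxel centres
  g <- make_fixture("cyl_channel", n = 61, spacing = 1 / 60, radius = 0.2)
  sk <- void_skeleton(g)
  idx <- which(sk$skeleton, arr.ind = TRUE)
  expect_gt(nrow(idx), 30)
  off <- sqrt((idx[, 1] - 31)^2 + (idx[, 2] - 31)^2)
  expect_lte(max(off), 1)                       # within one voxel of the axis

  pd <- pore_diameters(g)
  expect_equal(pd$d_min_um, pd$d_max_um)        # constant radius
  expect_equal(pd$d_max_um, 400, tolerance = 2 * (1000 / 60) / 400)
})

test_that("two channels of different radii set d_min and d_max", {
  g <- make_fixture("cyl_channel", n = 61, spacing = 1 / 60,
                    radius = c(0.05, 0.2),
                    centers = rbind(c(0.15, 0.5), c(0.65, 0.5)))
  pd <- pore_diameters(g, components = "all")
  expect_equal(pd$d_min_um, 100, tolerance = 0.35)
  expect_equal(pd$d_max_um, 400, tolerance = 0.1)
  expect_equal(pd$void_components, 2)
})

test_that("fully solid grids raise a no-void error", {
  solid <- make_fixture("solid_block", n = 10, spacing = 0.1)
  expect_error(void_skeleton(solid), "void")
  expect_error(pore_diameters(solid), "void")
})

test_that("TPMS void skeleton is thin, connected and topology-preserving", {
  g <- tpms_grid("gyroid", 0.5, 30, repetitions = 2L)
  sk <- void_skeleton(g)
  expect_gt(sk$skeleton_voxel_count, 0)
  expect_true(all(sk$skeleton <= !g$occupancy))  # subset of the void
  # skeleton of the largest void component stays 26-connected
  ncomp <- scaffopt:::.count_components_cpp(as.logical(sk$skeleton),
                                            dim(sk$skeleton), 26L)
  expect_equal(ncomp, 1)
  # thin: no fully occupied 2x2x2 block
  s <- sk$skeleton
  d <- dim(s)
  blocks <- s[-d[1], -d[2], -d[3]] & s[-1, -d[2], -d[3]] &
            s[-d[1], -1, -d[3]] & s[-1, -1, -d[3]] &
            s[-d[1], -d[2], -1] & s[-1, -d[2], -1] &
            s[-d[1], -1, -1] & s[-1, -1, -1]
  expect_false(any(blocks))
})

test_that("largest pore shrinks as material is added", {
  sw <- pore_sweep("gyroid", c(0.3, 0.5, 0.7), resolution = 40, tiling = 2)
  tol_um <- 2 * 1000 / 40   # one-voxel tolerance either way
  expect_true(all(diff(sw$d_max_um) <= tol_um))
})

test_that("pore diameters are robust to the analysis resolution", {
  a <- pore_sweep("gyroid", 0.5, resolution = 60, tiling = 3)
  b <- pore_sweep("gyroid", 0.5, resolution = 100, tiling = 3)
  expect_equal(a$d_max_um, b$d_max_um, tolerance = 0.1)
  # the smallest pore is an extreme-value statistic: the finer skeleton
  # reaches narrower throats, so it carries a wider spread
  expect_equal(a$d_min_um, b$d_min_um, tolerance = 0.15)
})

test_that("pore_window interpolates constraint crossings and flags exclusions", {
  # a synthetic check through the public sweep interface: primitive keeps
  # pores wider than 400 um at every volume fraction and must be discarded
  w <- pore_window("primitive", seq(0.3, 0.9, by = 0.3), resolution = 60)
  expect_true(w$empty)
  expect_match(w$reason, "exceeds|all VF")

  expect_error(pore_window("gyroid", c(0.5, 0.3)), "sorted|unsorted")
  expect_error(pore_window("gyroid", c(0.1, 0.5)), "0.2")
})
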