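test_that("init_phi places the interface at the scaffold surface", {
  sp <- make_fixture("spherical_pore", n = 40, spacing = 0.02, radius = 0.3)
  st <- init_phi(sp, periodic = FALSE)
  ctr <- round(dim(st$phi) / 2)
  # the nearest voxel centre sits up to half a voxel diagonal off the sphere
  # centre, so phi there is within about one spacing of -r
  expect_lt(abs(st$phi[ctr[1], ctr[2], ctr[3]] + 0.3), 1.5 * 0.02)
  expect_equal(st$initial_void_volume, sum(!sp$occupancy) * 0.02^3,
               tolerance = 0.05)
  expect_equal(st$time, 0)

  # plain occupancy grid (no smooth seed): voxel-centre distance convention
  occ <- array(TRUE, dim = c(10, 10, 10))
  occ[, , 6:10] <- FALSE
  st2 <- init_phi(voxel_grid(occ, 0.1), periodic = FALSE)
  expect_equal(st2$phi[5, 5, 5], 0.05)   # solid voxel touching the interface
  expect_error(init_phi(make_fixture("solid_block", n = 8, spacing = 0.1)),
               "void")
})

test_that("curvature has the analytic magnitude and sign convention", {
  # concave as seen from the void: +2/r inside a spherical pore
  sp <- make_fixture("spherical_pore", n = 48, spacing = 0.02, radius = 0.4)
  st <- init_phi(sp, periodic = FALSE)
  k <- curvature_field(st)
  iface <- abs(st$phi) < 0.02
  expect_equal(median(k[iface]), 2 / 0.4, tolerance = 0.1)

  # convex from the void: -2/r around a solid sphere
  ss <- solid_sphere_grid(n = 48, spacing = 0.02, radius = 0.4)
  st2 <- init_phi(ss, periodic = FALSE)
  k2 <- curvature_field(st2)
  iface2 <- abs(st2$phi) < 0.02
  expect_equal(median(k2[iface2]), -2 / 0.4, tolerance = 0.1)

  # flat interface: zero curvature
  sl <- make_fixture("slab_void", n = 24, spacing = 0.04)
  st3 <- init_phi(sl, periodic = FALSE)
  k3 <- curvature_field(st3)
  expect_lt(max(abs(k3[abs(st3$phi) < 0.08])), 1e-6)
})

test_that("flat and convex surfaces do not grow under the one-sided rule", {
  params <- growth_params(max_days = Inf)
  sl <- make_fixture("slab_void", n = 24, spacing = 1 / 24)
  st <- init_phi(sl, periodic = FALSE)
  phi0 <- st$phi
  st <- advect_step(st, params, n_steps = 10000)
  expect_equal(st$phi, phi0, tolerance = 1e-8)

  ss <- solid_sphere_grid(n = 24, spacing = 1 / 24, radius = 0.2)
  st2 <- init_phi(ss, periodic = FALSE)
  v0 <- sum(st2$phi >= 0)
  st2 <- advect_step(st2, params, n_steps = 10000)
  expect_equal(sum(st2$phi >= 0), v0)
})

test_that("shrinking pores follow the analytic curvature-flow clocks", {
  # spherical pore: dr/dtau = -2/r  =>  fill at about r0^2/4
  sp <- make_fixture("spherical_pore", n = 48, spacing = 0.02, radius = 0.3)
  cv <- simulate_growth(sp, growth_params(max_days = Inf), periodic = FALSE)
  expect_true(cv$filled)
  expect_lt(abs(cv$fill_time - 0.3^2 / 4) / (0.3^2 / 4), 0.1)

  # cylindrical channel: dr/dtau = -1/r  =>  fill at about r0^2/2
  ch <- make_fixture("cyl_channel", n = 49, spacing = 1 / 48, radius = 0.25)
  cv2 <- simulate_growth(ch, growth_params(max_days = Inf), periodic = FALSE)
  expect_true(cv2$filled)
  expect_lt(abs(cv2$fill_time - 0.25^2 / 2) / (0.25^2 / 2), 0.1)
})

test_that("tissue volume grows monotonically and is bounded by the void", {
  g <- tpms_grid("gyroid", 0.4, 32)
  cv <- simulate_growth(g, growth_params(max_days = Inf), periodic = TRUE)
  expect_true(cv$filled)
  expect_true(all(diff(cv$tissue_volumes) >= -1e-9))
  expect_lte(max(cv$tissue_volumes), cv$initial_void_volume * (1 + 1e-6))
})

test_that("rates rescale exactly linearly in the velocity coefficient", {
  g <- tpms_grid("gyroid", 0.5, 32)
  c1 <- simulate_growth(g, growth_params(max_days = Inf, lambda_coef = 1),
                        periodic = TRUE)
  c2 <- simulate_growth(g, growth_params(max_days = Inf, lambda_coef = 2),
                        periodic = TRUE)
  expect_equal(c2$times * 2, c1$times, tolerance = 1e-12)
  expect_equal(c2$tissue_volumes, c1$tissue_volumes, tolerance = 1e-12)
  expect_equal(average_growth_rate(c2), 2 * average_growth_rate(c1),
               tolerance = 1e-12)
  expect_equal(calibrate_lambda(c1, average_growth_rate(c2)), 2,
               tolerance = 1e-12)
})

test_that("average rate is void volume over fill time, undefined when unfilled", {
  filled <- structure(list(filled = TRUE, fill_time = 6,
                           initial_void_volume = 0.51, lambda_coef = 1),
                      class = "growth_curve")
  expect_equal(average_growth_rate(filled), 0.085)

  unfilled <- structure(list(filled = FALSE, fill_time = NA,
                             initial_void_volume = 0.51, lambda_coef = 1),
                        class = "growth_curve")
  expect_warning(r <- average_growth_rate(unfilled), "undefined|not filled")
  expect_true(is.na(r))
  expect_error(calibrate_lambda(unfilled, 0.08), "unfilled")
})

test_that("convergence study reports rates and successive changes", {
  mkfix <- function(res) make_fixture("spherical_pore", n = res,
                                      spacing = 0.96 / res, radius = 0.3)
  tab <- convergence_study(mkfix, c(24, 24, 40), periodic = FALSE,
                           params = growth_params(max_days = Inf))
  expect_equal(nrow(tab), 3)
  expect_true(is.na(tab$rel_change[1]))
  expect_equal(tab$rel_change[2], 0)          # identical grids, zero change
  expect_true(tab$converged[2])
  expect_error(convergence_study(mkfix, c(24, 40)), "3 resolutions")
})
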