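test_that("homogeneous and laminate fixtures reproduce closed-form moduli", {
  sb <- make_fixture("solid_block", n = 12, spacing = 1 / 12)
  expect_equal(as.numeric(voxel_modulus(fe_problem(sb))), 1, tolerance = 0.01)

  # walls aligned with the load attain the Voigt bound E* = rho
  lp <- make_fixture("laminate_parallel", n = 16, spacing = 1 / 16,
                     solid_frac = 0.5)
  expect_equal(as.numeric(voxel_modulus(fe_problem(lp))), 0.5,
               tolerance = 0.01)

  # a void layer normal to the load cannot transmit it
  ls <- make_fixture("laminate_series", n = 12, spacing = 1 / 12,
                     solid_frac = 0.5)
  expect_warning(e <- voxel_modulus(fe_problem(ls)), "percolate")
  expect_equal(as.numeric(e), 0)
})

test_that("fe_problem validates material parameters", {
  sb <- make_fixture("solid_block", n = 8, spacing = 0.1)
  expect_error(fe_problem(sb, nu = 0.6), "poisson")
  expect_error(fe_problem(sb, applied_strain = 0), "strain")
})

test_that("scaffold moduli respect the Voigt bound and cubic symmetry", {
  for (vf in c(0.3, 0.6)) {
    g <- tpms_grid("gyroid", vf, 16)
    e <- as.numeric(voxel_modulus(fe_problem(g)))
    expect_gt(e, 0)
    expect_lte(e, volume_fraction(g) + 0.01)
  }
  g <- tpms_grid("gyroid", 0.5, 16)
  ez <- as.numeric(voxel_modulus(fe_problem(g)))
  gx <- g
  gx$occupancy <- aperm(g$occupancy, c(3, 1, 2))  # load along former x axis
  ex <- as.numeric(voxel_modulus(fe_problem(gx)))
  expect_equal(ex, ez, tolerance = 0.02)
})

test_that("modulus is mesh-convergent and monotone in volume fraction", {
  # doubling the resolution from a sheet-resolving grid moves E* by < 5%
  e16 <- as.numeric(voxel_modulus(fe_problem(tpms_grid("gyroid", 0.5, 16))))
  e32 <- as.numeric(voxel_modulus(fe_problem(tpms_grid("gyroid", 0.5, 32))))
  expect_equal(e32, e16, tolerance = 0.05)

  es <- vapply(c(0.3, 0.5, 0.7), function(vf)
    as.numeric(voxel_modulus(fe_problem(tpms_grid("gyroid", vf, 16)))),
    numeric(1))
  expect_true(all(diff(es) > 0))
})

test_that("sweep over parallel laminates fits an essentially linear law", {
  vf <- c(0.25, 0.375, 0.5, 0.625, 0.75)
  es <- vapply(vf, function(r)
    as.numeric(voxel_modulus(fe_problem(
      make_fixture("laminate_parallel", n = 16, spacing = 1 / 16,
                   solid_frac = r)))), numeric(1))
  law <- fit_scaling_law(vf, es, "laminate")
  expect_equal(law$C1, 1, tolerance = 0.1)
  expect_lt(law$n_exp, 1.1)
  expect_equal(law$E0, 0, tolerance = 0.05)
})
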