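test_that("relative modulus evaluates the Gibson-Ashby law", {
  laws <- default_scaling_laws()
  expect_equal(relative_modulus(laws$gyroid, 0.5),
               1.33 * 0.5^2.68 - 0.002, tolerance = 1e-12)
  expect_equal(relative_modulus(laws$diamond, 0.2),
               1.26 * 0.2^2.74 + 0.039, tolerance = 1e-12)
  expect_equal(relative_modulus(laws$gyroid, 0.5), 0.2055, tolerance = 1e-3)

  expect_error(relative_modulus(laws$gyroid, 0.1), "range")
  # split P offset pushes the law negative at the bottom of the range
  expect_warning(e <- relative_modulus(laws$split_p, 0.2), "clip")
  expect_equal(e, 0)
})

test_that("all shipped laws increase strictly wherever they are positive", {
  vf <- seq(0.2, 0.9, by = 0.01)
  for (law in default_scaling_laws()) {
    e <- law$C1 * vf^law$n_exp + law$E0    # unclipped form
    expect_true(all(diff(e) > 0), label = law$tpms_type)
    clipped <- suppressWarnings(relative_modulus(law, vf))
    expect_true(all(diff(clipped) >= 0), label = paste(law$tpms_type, "clipped"))
  }
})

test_that("axial stiffness follows k = E* E piD^2/(4L) with unit discipline", {
  env <- stiffness_envelope()
  expect_equal(axial_stiffness(0, env), 0)
  expect_equal(axial_stiffness(1, env), 1800 * pi * 900 / 120)  # ~42412 N/mm
  expect_equal(axial_stiffness(0.4, env), 2 * axial_stiffness(0.2, env))
})

test_that("stiffness window inverts the law and round-trips the bounds", {
  law <- default_scaling_laws()$gyroid
  wide <- stiffness_window(law, stiffness_envelope(k_lo = 1e-9, k_hi = 1e12))
  expect_equal(c(wide$lo, wide$hi), c(0.2, 0.9))

  env <- stiffness_envelope()
  w <- stiffness_window(law, env)
  expect_false(w$empty)
  for (edge_k in list(c(w$lo, env$k_lo), c(w$hi, env$k_hi))) {
    if (edge_k[1] > 0.2 && edge_k[1] < 0.9) {
      k <- axial_stiffness(relative_modulus(law, edge_k[1]), env)
      expect_equal(k, edge_k[2], tolerance = 1e-6)
    }
  }
})

test_that("widening the stiffness limits never shrinks the window", {
  law <- default_scaling_laws()$lidinoid
  narrow <- stiffness_window(law, stiffness_envelope(k_lo = 1500, k_hi = 2000))
  wide <- stiffness_window(law, stiffness_envelope(k_lo = 1000, k_hi = 2700))
  expect_lte(wide$lo, narrow$lo)
  expect_gte(wide$hi, narrow$hi)
})

test_that("fit recovers known scaling constants", {
  vf <- seq(0.2, 0.9, by = 0.1)
  truth <- default_scaling_laws()$gyroid
  e <- truth$C1 * vf^truth$n_exp + truth$E0

  fit <- fit_scaling_law(vf, e, "gyroid")
  expect_equal(fit$C1, truth$C1, tolerance = 1e-6)
  expect_equal(fit$n_exp, truth$n_exp, tolerance = 1e-6)
  expect_equal(fit$E0, truth$E0, tolerance = 1e-6)

  set.seed(3)
  noisy <- fit_scaling_law(vf, e + rnorm(length(e), sd = 0.005), "gyroid")
  expect_equal(noisy$n_exp, truth$n_exp, tolerance = 0.1 / truth$n_exp)

  expect_error(fit_scaling_law(vf[1:3], e[1:3]), "4 data points")
})
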