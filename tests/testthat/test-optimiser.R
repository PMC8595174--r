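test_that("window intersection is commutative, idempotent and absorbs empties", {
  a <- structure(list(lo = 0.3, hi = 0.6, empty = FALSE, reason = NA),
                 class = "vf_window")
  b <- structure(list(lo = 0.5, hi = 0.8, empty = FALSE, reason = NA),
                 class = "vf_window")
  ab <- window_intersect(a, b)
  ba <- window_intersect(b, a)
  expect_equal(c(ab$lo, ab$hi), c(0.5, 0.6))
  expect_equal(c(ba$lo, ba$hi), c(0.5, 0.6))
  expect_equal(window_intersect(a, a)[c("lo", "hi")], a[c("lo", "hi")])
  expect_null(window_intersect(NULL, NULL))
  expect_equal(window_intersect(a, NULL)[c("lo", "hi")], a[c("lo", "hi")])

  disjoint <- structure(list(lo = 0.7, hi = 0.9, empty = FALSE, reason = NA),
                        class = "vf_window")
  expect_true(window_intersect(a, disjoint)$empty)
  expect_true(window_intersect(window_intersect(a, disjoint), b)$empty)
})

test_that("manual window source carries supplied windows through", {
  cfg <- default_config(types = c("lidinoid", "split_p"),
                        optimise = list(window_source = "manual",
                                        manual_windows = reference_vf_windows()))
  w <- constraint_windows(cfg)
  expect_equal(c(w$lidinoid$final$lo, w$lidinoid$final$hi), c(0.49, 0.59))
  expect_equal(c(w$split_p$final$lo, w$split_p$final$hi), c(0.44, 0.54))
  expect_false(w$lidinoid$excluded)
  # the stiffness window is still reported alongside
  expect_false(is.null(w$lidinoid$stiffness))

  bad <- default_config(types = "gyroid",
                        optimise = list(window_source = "manual"))
  expect_error(constraint_windows(bad), "manual_windows")
})

test_that("unconstrained stiffness limits give the full window for shipped laws", {
  cfg <- default_config(types = c("gyroid", "split_p", "diamond", "lidinoid"),
                        stiffness = list(k_lo = 0, k_hi = Inf),
                        optimise = list(window_source = "stiffness"))
  w <- constraint_windows(cfg)
  for (ty in names(w)) {
    expect_equal(c(w[[ty]]$final$lo, w[[ty]]$final$hi), c(0.2, 0.9),
                 label = ty)
  }
})

test_that("select_optimum takes the in-window argmax with lower-VF ties", {
  windows <- list(
    a = list(final = scaffopt:::.vf_window(0.3, 0.5), excluded = FALSE,
             reason = NA),
    b = list(final = scaffopt:::.vf_window(0.4, 0.6), excluded = FALSE,
             reason = NA),
    c = list(final = NULL, excluded = TRUE, reason = "max pore > 400 um"))
  rates <- rbind(
    data.frame(type = "a", vf = c(0.3, 0.4, 0.5), rate = c(9, 7, 5),
               filled = TRUE),                          # decreasing
    data.frame(type = "b", vf = c(0.4, 0.5, 0.6), rate = c(4, 6, 6),
               filled = TRUE))                          # tied maximum
  opt <- select_optimum(rates, windows)
  expect_equal(opt$optimal_vf[opt$type == "a"], 0.3)    # window lower edge
  expect_equal(opt$optimal_vf[opt$type == "b"], 0.5)    # lower VF on tie
  expect_equal(opt$rank[opt$type == "a"], 1L)
  expect_true(opt$excluded[opt$type == "c"])
  expect_match(opt$reason[opt$type == "c"], "pore")
})

test_that("growth sweep includes window edges and is cached", {
  cfg <- default_config(types = "gyroid",
                        growth = list(resolution = 32),
                        optimise = list(vf_step = 0.05))
  w <- scaffopt:::.vf_window(0.42, 0.53)
  t0 <- proc.time()[3]
  sw1 <- growth_sweep("gyroid", w, cfg)
  t1 <- proc.time()[3]
  sw2 <- growth_sweep("gyroid", w, cfg)
  t2 <- proc.time()[3]
  expect_setequal(sw1$vf, c(0.42, 0.45, 0.5, 0.53))
  expect_true(all(sw1$filled))
  expect_identical(sw1, sw2)
  expect_lt(t2 - t1, (t1 - t0) / 5)   # second pass served from cache

  # the optimal VF is invariant to the velocity coefficient
  cfg2 <- default_config(types = "gyroid",
                         growth = list(resolution = 32, lambda_coef = 2),
                         optimise = list(vf_step = 0.05))
  sw3 <- growth_sweep("gyroid", w, cfg2)
  expect_equal(sw3$rate, 2 * sw1$rate, tolerance = 1e-12)
  expect_equal(which.max(sw3$rate), which.max(sw1$rate))
})

test_that("report writes deterministic CSV artefacts with exclusion reasons", {
  cfg <- default_config(types = c("gyroid", "primitive"),
                        growth = list(resolution = 32),
                        optimise = list(window_source = "manual",
                                        manual_windows = list(gyroid = c(0.45, 0.5))))
  res <- optimise_scaffold(cfg)
  expect_s3_class(res, "scaffopt_result")
  expect_true(res$optima$excluded[res$optima$type == "primitive"])

  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  suppressWarnings(report(res, out1))
  suppressWarnings(report(res, out2))
  for (f in c("optimal_designs.csv", "constraint_windows.csv",
              "growth_rates.csv", "scaling_laws.csv", "stiffness_curves.csv")) {
    expect_true(file.exists(file.path(out1, f)), label = f)
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  opt <- read.csv(file.path(out1, "optimal_designs.csv"))
  expect_true(all(c("type", "optimal_vf", "max_rate", "excluded", "reason")
                  %in% names(opt)))
  expect_match(opt$reason[opt$type == "primitive"], "manual|window")
  expect_true(file.exists(file.path(out1, "manifest.yaml")))
})
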