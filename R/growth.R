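#' Parameters of the curvature-driven growth model
#'
#' Tissue advances from the scaffold surface into the void with normal speed
#' proportional to the local mean curvature where the surface is concave as
#' seen from the void, and zero speed on flat or convex regions (the one-sided
#' velocity rule). The simulation integrates the dimensionless curvature flow
#' (unit velocity-curvature coefficient); `lambda_coef`, in mm^2/day, converts
#' dimensionless time tau to physical days (`days = tau / lambda_coef`) and is
#' the single constant that must be calibrated against an observed growth rate
#' (see [calibrate_lambda()]). Growth-rate *ratios* between scaffold designs
#' are independent of it.
#'
#' @param dt Dimensionless time step (default 1e-4; sub-divided further
#'   whenever the CFL limit demands it).
#' @param lambda_coef Velocity-curvature coefficient, mm^2/day (default 1).
#' @param max_days Simulation horizon in days (default 21).
#' @param fill_threshold Remaining-void fraction defining "filled"
#'   (default 0.005).
#' @param redistance_interval Steps between signed-distance redistancing
#'   passes (fast marching with subcell interface initialisation; default 5 --
#'   the speed field is trusted only in a tight interface band, so the
#'   distance property must be refreshed before the interface can leave it).
#' @param reinit_iters Retained for API stability (the fast-marching
#'   redistancer is direct, not iterative).
#' @param out_every Steps between recorded volume samples.
#' @param band_mult Narrow-band half-width in voxel spacings within which the
#'   speed field is evaluated (default 3).
#' @param cfl CFL safety factor (default 0.45).
#' @return Object of class `growth_params`.
#' @export
growth_params <- function(dt = 1e-4, lambda_coef = 1, max_days = 21,
                          fill_threshold = 0.005, redistance_interval = 10,
                          reinit_iters = 12, out_every = 5, band_mult = 6,
                          cfl = 0.45) {
  if (dt <= 0) stop("dt must be > 0")
  if (lambda_coef <= 0) stop("lambda_coef must be > 0")
  if (!(fill_threshold > 0 && fill_threshold < 1))
    stop("fill_threshold must lie in (0, 1)")
  structure(list(dt = dt, lambda_coef = lambda_coef, max_days = max_days,
                 fill_threshold = fill_threshold,
                 redistance_interval = redistance_interval,
                 reinit_iters = reinit_iters, out_every = out_every,
                 band_mult = band_mult, cfl = cfl),
            class = "growth_params")
}

# signed distance, optionally with periodic wrap handled by padding
.signed_distance_occ <- function(occ, h, periodic) {
  d <- dim(occ)
  if (!periodic) {
    d_solid <- sqrt(.edt_sq_cpp(as.logical(occ), d))
    d_void <- sqrt(.edt_sq_cpp(!as.logical(occ), d))
    phi <- ifelse(as.logical(occ), d_void * h - h / 2, -(d_solid * h - h / 2))
    return(array(phi, dim = d))
  }
  pad <- pmin(d, 32L)
  ix <- ((seq(1 - pad[1], d[1] + pad[1]) - 1) %% d[1]) + 1
  iy <- ((seq(1 - pad[2], d[2] + pad[2]) - 1) %% d[2]) + 1
  iz <- ((seq(1 - pad[3], d[3] + pad[3]) - 1) %% d[3]) + 1
  occ_p <- occ[ix, iy, iz]
  dp <- dim(occ_p)
  d_solid <- sqrt(.edt_sq_cpp(as.logical(occ_p), dp))
  d_void <- sqrt(.edt_sq_cpp(!as.logical(occ_p), dp))
  phi <- ifelse(as.logical(occ_p), d_void * h - h / 2, -(d_solid * h - h / 2))
  phi <- array(phi, dim = dp)
  phi[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])]
}

#' Initialise the level-set state from a voxel grid
#'
#' The interface is placed exactly at the scaffold surface: `phi` is the
#' signed Euclidean distance to the solid/void interface, positive inside the
#' solid (and, later, tissue) phase. Tissue volume starts at zero.
#'
#' When the grid carries a smooth level-set seed (grids built by [voxelize()]
#' or [make_fixture()] do), the distance field is rebuilt from the seed's
#' sub-voxel zero crossings by fast marching, so the interface -- and hence
#' the curvature that drives growth -- reflects the true smooth surface
#' rather than the voxel staircase. A curvature-rectifying velocity amplifies
#' staircase noise, so this matters; grids lacking a seed fall back to the
#' voxel-centre distance transform.
#'
#' @param grid A [voxel_grid()] containing void.
#' @param periodic Treat the grid as one period of an infinite lattice
#'   (default TRUE, the scaffold case); use FALSE for bounded fixtures.
#' @return Object of class `level_set_state`.
#' @export
init_phi <- function(grid, periodic = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- grid$occupancy
  if (!any(!occ)) stop("no void: nothing to grow into")
  h <- grid$spacing
  phi <- if (isTRUE(grid$phi_exact)) {
    grid$phi_seed                    # analytic signed distance: use directly
  } else if (!is.null(grid$phi_seed)) {
    # normalise the smooth seed to a signed distance near the interface
    # (interface-pinned reinitialisation; curvature only needs the field to
    # be smooth and well-scaled within the narrow band)
    array(.reinit_cpp(as.numeric(grid$phi_seed), dim(occ), h, periodic, 40L),
          dim = dim(occ))
  } else {
    .signed_distance_occ(occ, h, periodic)
  }
  voxvol <- h^3
  total <- length(occ) * voxvol
  solid0 <- sum(occ) * voxvol
  structure(list(phi = phi, spacing = h, periodic = periodic, tau = 0,
                 time = 0, initial_solid_volume = solid0,
                 initial_void_volume = total - solid0),
            class = "level_set_state")
}

#' @export
print.level_set_state <- function(x, ...) {
  cat(sprintf("level_set_state: %s grid, tau = %.4g, t = %.4g days, void0 = %.4g mm^3\n",
              paste(dim(x$phi), collapse = " x "), x$tau, x$time,
              x$initial_void_volume))
  invisible(x)
}

#' Mean curvature of the interface neighbourhood
#'
#' Central-difference divergence of the normalised gradient of `phi`,
#' `k = div(grad phi / |grad phi|)`, in 1/mm. Positive on surfaces concave as
#' seen from the void (e.g. inside a pore); where the gradient magnitude
#' vanishes the curvature is set to zero (zero velocity there).
#'
#' @param state A [init_phi()] state (redistanced `phi`).
#' @return Numeric 3-D array of curvatures.
#' @export
curvature_field <- function(state) {
  stopifnot(inherits(state, "level_set_state"))
  array(.curvature_cpp(as.numeric(state$phi), dim(state$phi), state$spacing,
                       state$periodic),
        dim = dim(state$phi))
}

#' Advance the interface a fixed number of steps
#'
#' First-order upwind advection of `phi` with normal speed
#' `F = lambda * max(k, 0)`; the step is sub-divided whenever the CFL
#' condition demands it, and the signed-distance property is restored every
#' `redistance_interval` steps.
#'
#' @param state A `level_set_state`.
#' @param params A [growth_params()].
#' @param n_steps Number of steps to take (default 1).
#' @return The advanced state.
#' @export
advect_step <- function(state, params = growth_params(), n_steps = 1) {
  stopifnot(inherits(state, "level_set_state"))
  h <- state$spacing
  core <- .growth_core_cpp(as.numeric(state$phi), dim(state$phi), h,
                           state$periodic, params$dt, Inf,
                           as.integer(n_steps), params$fill_threshold,
                           FALSE, params$redistance_interval,
                           params$reinit_iters, as.integer(params$out_every),
                           params$band_mult * h, params$cfl)
  state$phi <- array(core$phi, dim = dim(state$phi))
  state$tau <- state$tau + max(core$tau)
  state$time <- state$tau / params$lambda_coef
  state
}

#' Simulate curvature-driven tissue growth
#'
#' Runs the level-set model until the void is filled (remaining void below
#' `fill_threshold` of the initial void volume), growth plateaus (residual
#' surfaces flat or convex), or the `max_days` horizon is reached. The average
#' growth rate is the initial void volume divided by the fill time and is
#' reported only for filled runs.
#'
#' @param grid A [voxel_grid()].
#' @param params A [growth_params()].
#' @param periodic Passed to [init_phi()] (default TRUE).
#' @return Object of class `growth_curve`: `times` (days), `tissue_volumes`
#'   (mm^3), `fill_time` (days or NA), `average_rate` (mm^3/day or NA),
#'   `filled`, `initial_void_volume`, `lambda_coef`, `steps`.
#' @export
simulate_growth <- function(grid, params = growth_params(), periodic = TRUE) {
  state <- init_phi(grid, periodic = periodic)
  h <- state$spacing
  lam <- params$lambda_coef
  tau_max <- params$max_days * lam
  max_steps <- 500000L
  core <- .growth_core_cpp(as.numeric(state$phi), dim(state$phi), h,
                           state$periodic, params$dt, tau_max, max_steps,
                           params$fill_threshold, TRUE,
                           params$redistance_interval, params$reinit_iters,
                           as.integer(params$out_every),
                           params$band_mult * h, params$cfl)
  fill_time <- if (isTRUE(core$filled)) core$fill_tau / lam else NA_real_
  structure(list(times = core$tau / lam,
                 tissue_volumes = core$tissue,
                 fill_time = fill_time,
                 average_rate = if (is.na(fill_time)) NA_real_
                                else core$void_vol0 / fill_time,
                 filled = isTRUE(core$filled),
                 stalled = isTRUE(core$stalled),
                 initial_void_volume = core$void_vol0,
                 initial_solid_volume = core$solid_vol0,
                 lambda_coef = lam, steps = core$steps),
            class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  if (x$filled)
    cat(sprintf("growth_curve: filled %.4g mm^3 in %.3g days (avg %.4g mm^3/day, %d steps)\n",
                x$initial_void_volume, x$fill_time, x$average_rate, x$steps))
  else
    cat(sprintf("growth_curve: not filled (%.1f%% grown, %d steps%s)\n",
                100 * max(x$tissue_volumes) / x$initial_void_volume, x$steps,
                if (x$stalled) ", plateaued" else ""))
  invisible(x)
}

#' Average growth rate of a filled curve
#'
#' Initial void volume divided by the time taken to fill it.
#'
#' @param curve A [simulate_growth()] result.
#' @return Rate in mm^3/day; `NA` with a warning when the void never filled
#'   within the horizon.
#' @export
average_growth_rate <- function(curve) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!curve$filled) {
    warning("void not filled within the simulation horizon; rate undefined")
    return(NA_real_)
  }
  curve$initial_void_volume / curve$fill_time
}

#' Calibrate the velocity-curvature coefficient
#'
#' The growth PDE is linear in time under rescaling of `lambda`, so a curve
#' simulated with coefficient `lambda0` that yields average rate `r0` implies
#' the coefficient `lambda0 * target_rate / r0` would reproduce `target_rate`
#' exactly. This performs that single-point calibration.
#'
#' @param curve A filled [simulate_growth()] result.
#' @param target_rate Observed average growth rate, mm^3/day.
#' @return The calibrated `lambda_coef` (mm^2/day).
#' @export
calibrate_lambda <- function(curve, target_rate) {
  stopifnot(inherits(curve, "growth_curve"))
  if (!curve$filled) stop("cannot calibrate on an unfilled growth curve")
  if (target_rate <= 0) stop("target_rate must be > 0")
  curve$lambda_coef * target_rate / average_growth_rate(curve)
}

#' Grid-convergence study of the growth rate
#'
#' Simulates one scaffold at increasing voxel resolutions and reports the
#' average growth rate per resolution together with the successive relative
#' change, flagging the first resolution at which that change drops below
#' `criterion` (default 1%).
#'
#' @param spec A [scaffold_spec()] (or a fixture-producing function taking a
#'   resolution and returning a [voxel_grid()]).
#' @param resolutions Ascending voxels-per-cell values (>= 3 of them).
#' @param params A [growth_params()].
#' @param periodic Passed to [simulate_growth()].
#' @param criterion Relative-change threshold (default 0.01).
#' @return data.frame with `resolution`, `voxels`, `rate`, `rel_change`,
#'   `converged`.
#' @export
convergence_study <- function(spec, resolutions, params = growth_params(),
                              periodic = TRUE, criterion = 0.01) {
  if (length(resolutions) < 3) stop("need at least 3 resolutions")
  if (is.unsorted(resolutions)) stop("resolutions must be ascending")
  rates <- vapply(resolutions, function(res) {
    grid <- if (is.function(spec)) spec(res) else voxelize(spec, res)
    curve <- simulate_growth(grid, params, periodic = periodic)
    average_growth_rate(curve)
  }, numeric(1))
  voxels <- if (is.function(spec)) rep(NA_integer_, length(resolutions)) else
    as.integer(round(resolutions^3 * prod(spec$repetitions)))
  rel <- c(NA, abs(diff(rates)) / abs(rates[-length(rates)]))
  data.frame(resolution = resolutions, voxels = voxels, rate = rates,
             rel_change = rel,
             converged = !is.na(rel) & rel < criterion)
}
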