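# Shared helpers: small grids built in code; heavy sweep results are memoised
# by the package's own cache, so repeated use across test files is cheap.

tpms_grid <- function(type, vf, resolution, repetitions = 1L) {
  t <- calibrate_t(type, vf, resolution = resolution)
  voxelize(scaffold_spec(type, t, repetitions = repetitions), resolution)
}

# dimensionless average growth rate of one periodic unit cell
unit_cell_rate <- function(type, vf, resolution = 64, ...) {
  grid <- tpms_grid(type, vf, resolution)
  curve <- simulate_growth(grid, growth_params(max_days = Inf, ...),
                           periodic = TRUE)
  if (!curve$filled) return(NA_real_)
  curve$average_rate
}

# solid sphere surrounded by void (convex interface as seen from the void)
solid_sphere_grid <- function(n = 32, spacing = 0.02, radius = NULL) {
  g <- make_fixture("spherical_pore", n = n, spacing = spacing,
                    radius = radius %||% (n * spacing / 4))
  g$occupancy <- !g$occupancy
  g$phi_seed <- -g$phi_seed
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
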