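#' @useDynLib scaffopt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif setNames
#' @importFrom utils modifyList read.csv write.csv
NULL

#' Supported TPMS lattice types
#'
#' The six sheet-solid triply periodic minimal surface families handled by the
#' package: Primitive, Gyroid, Split P, Diamond, Lidinoid and Neovius.
#'
#' @return Character vector of type identifiers.
#' @export
tpms_types <- function() {
  c("primitive", "gyroid", "split_p", "diamond", "lidinoid", "neovius")
}

.tpms_type_code <- function(tpms_type) {
  code <- match(match.arg(tolower(tpms_type), tpms_types()), tpms_types())
  if (is.na(code)) stop("unsupported TPMS type: ", tpms_type)
  code
}

#' Symbolic definition of one scaffold design
#'
#' A `scaffold_spec` describes a sheet-TPMS scaffold: the lattice type, the
#' level-set threshold `t` controlling volume fraction (the solid phase is
#' `|f| <= t`, i.e. the matrix between the two offset isosurfaces `f = +/-t`),
#' the unit-cell edge length in mm and the number of cell repetitions per
#' axis. Periodicities `k_i = 2*pi*n_i` are derived from the repetitions and
#' never stored.
#'
#' @param tpms_type One of [tpms_types()].
#' @param t Non-negative dimensionless threshold.
#' @param cell_size Unit-cell edge length in mm (default 1).
#' @param repetitions Integer cell counts per axis; length 1 or 3.
#' @return An object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(tpms_type, t, cell_size = 1, repetitions = 1L) {
  tpms_type <- match.arg(tolower(tpms_type), tpms_types())
  if (!is.numeric(t) || length(t) != 1 || t < 0) stop("t must be a scalar >= 0")
  if (cell_size <= 0) stop("cell_size must be > 0")
  repetitions <- as.integer(rep(repetitions, length.out = 3))
  if (any(repetitions < 1)) stop("all repetitions must be >= 1")
  structure(list(tpms_type = tpms_type, t = t, cell_size = cell_size,
                 repetitions = repetitions),
            class = "scaffold_spec")
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat(sprintf("scaffold_spec: %s, t = %.4g, cell %.3g mm, %d x %d x %d cells\n",
              x$tpms_type, x$t, x$cell_size,
              x$repetitions[1], x$repetitions[2], x$repetitions[3]))
  invisible(x)
}

#' Evaluate a TPMS implicit field
#'
#' Returns the raw field `f` and the thresholded value `U = f^2 - t^2` at
#' arbitrary points. The solid (sheet) phase is `U <= 0`, equivalently
#' `|f| <= t`. Fields are periodic with period `cell_size` along each axis.
#'
#' @param tpms_type One of [tpms_types()].
#' @param point Numeric length-3 vector or an n x 3 matrix of mm coordinates.
#' @param t Threshold used for `U` (default 0).
#' @param cell_size Unit-cell edge in mm.
#' @return A data.frame with columns `f` and `U`.
#' @export
field_value <- function(tpms_type, point, t = 0, cell_size = 1) {
  code <- .tpms_type_code(tpms_type)
  if (cell_size <= 0) stop("cell_size must be > 0")
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  if (ncol(p) != 3) stop("point must have 3 coordinates")
  f <- vapply(seq_len(nrow(p)), function(i) {
    .tpms_field_grid_cpp(code, p[i, 1], p[i, 2], p[i, 3], cell_size)
  }, numeric(1))
  data.frame(f = f, U = f^2 - t^2)
}

#' Construct a voxel grid
#'
#' The shared discrete scaffold representation: a 3-D logical occupancy array
#' (`TRUE` = solid) with isotropic physical voxel spacing. The physical centre
#' of voxel `(i, j, k)` (1-based array indices) is
#' `origin + (i - 1/2, j - 1/2, k - 1/2) * spacing`.
#'
#' @param occupancy 3-D logical array.
#' @param spacing Voxel edge length, mm.
#' @param origin mm offset of the grid corner (default `c(0, 0, 0)`).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(occupancy, spacing, origin = c(0, 0, 0)) {
  if (length(dim(occupancy)) != 3) stop("occupancy must be a 3-D array")
  if (any(dim(occupancy) < 2)) stop("grid must be at least 2 voxels per axis")
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a positive scalar")
  storage.mode(occupancy) <- "logical"
  structure(list(occupancy = occupancy, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf("voxel_grid: %d x %d x %d voxels, spacing %.5g mm, VF %.4f\n",
              d[1], d[2], d[3], x$spacing, volume_fraction(x)))
  invisible(x)
}

#' Measured volume fraction of a voxel grid
#'
#' @param grid A [voxel_grid()].
#' @return Solid voxel count / total voxel count.
#' @export
volume_fraction <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  mean(grid$occupancy)
}

# voxel-centre coordinates along one axis
.axis_centres <- function(n, spacing, origin) origin + (seq_len(n) - 0.5) * spacing

# raw field sampled at the voxel centres of a grid covering
# repetitions*cell_size per axis at `resolution` voxels per cell
.field_on_grid <- function(tpms_type, resolution, repetitions, cell_size) {
  code <- .tpms_type_code(tpms_type)
  n <- resolution * rep(repetitions, length.out = 3)
  h <- cell_size / resolution
  x <- .axis_centres(n[1], h, 0)
  y <- .axis_centres(n[2], h, 0)
  z <- .axis_centres(n[3], h, 0)
  array(.tpms_field_grid_cpp(code, x, y, z, cell_size), dim = n)
}

#' Calibrate the threshold t for a target volume fraction
#'
#' Solves `VF(t) = target_vf` against the volume fraction measured on a
#' voxelised unit cell (the solid-classification rule is the same one
#' [voxelize()] applies, so the calibrated `t` reproduces `target_vf` at this
#' resolution). `VF(t)` is a non-decreasing step function of `t`, so the
#' bisection this performs has an exact fixed point: the sampled field value
#' whose achievable volume fraction is closest to the target, which is
#' returned directly. On coarse grids the achievable volume fractions are
#' quantised (grid symmetries tie many field values), so the achieved VF can
#' legitimately sit further from the target than `tol`; an error is raised
#' only when it is off by more than one quantisation step.
#'
#' @param tpms_type One of [tpms_types()].
#' @param target_vf Target volume fraction in `[0, 1]`.
#' @param resolution Voxels per unit cell used for the measurement.
#' @param cell_size Unit-cell edge, mm.
#' @param tol Volume-fraction tolerance (default 1e-3).
#' @return The calibrated threshold `t`.
#' @export
calibrate_t <- function(tpms_type, target_vf, resolution = 100, cell_size = 1,
                        tol = 1e-3) {
  if (target_vf < 0 || target_vf > 1) stop("target_vf must lie in [0, 1]")
  if (target_vf == 0) return(0)
  af <- abs(.field_on_grid(tpms_type, resolution, 1L, cell_size))
  if (target_vf >= 1) return(max(af))
  u <- sort(unique(as.vector(af)))
  vf_u <- cumsum(tabulate(match(af, u), nbins = length(u))) / length(af)
  i <- findInterval(target_vf, vf_u)           # largest index with VF <= target
  cand <- unique(pmin(pmax(c(i, i + 1L), 1L), length(u)))
  best <- cand[which.min(abs(vf_u[cand] - target_vf))]
  achieved <- vf_u[best]
  gap <- if (length(cand) == 2) diff(vf_u[cand]) else 1
  if (abs(achieved - target_vf) > max(tol, gap))
    stop(sprintf(
      "calibrate_t did not converge: target VF %.4f, achieved %.4f at resolution %d",
      target_vf, achieved, resolution))
  u[best]
}

#' Voxelise a scaffold
#'
#' Samples `U = f^2 - t^2` at voxel centres; a voxel is solid iff `U <= 0`
#' (boundary voxels count as solid for determinacy). Grid dimensions are
#' `resolution * repetitions` per axis with spacing `cell_size / resolution`.
#'
#' @param spec A [scaffold_spec()].
#' @param resolution Voxels per unit cell (>= 8).
#' @param max_voxels Memory guard: refuse larger grids (default 1.6e8).
#' @return A [voxel_grid()].
#' @export
voxelize <- function(spec, resolution, max_voxels = 1.6e8) {
  stopifnot(inherits(spec, "scaffold_spec"))
  if (resolution < 8) stop("resolution must be >= 8 voxels per cell")
  n <- resolution * spec$repetitions
  if (prod(n) > max_voxels)
    stop(sprintf("grid of %d voxels exceeds the budget of %g; raise max_voxels deliberately",
                 prod(n), max_voxels))
  f <- .field_on_grid(spec$tpms_type, resolution, spec$repetitions, spec$cell_size)
  g <- voxel_grid(abs(f) <= spec$t, spacing = spec$cell_size / resolution)
  # smooth level-set seed (positive in solid, zero on the true isosurface):
  # downstream interface analyses use its sub-voxel crossings rather than the
  # staircase of the boolean occupancy
  g$phi_seed <- array(spec$t - abs(f), dim = dim(g$occupancy))
  g
}

#' Analytic fixture geometries
#'
#' Test shapes with known pore diameters, elastic moduli and curvature-flow
#' behaviour: a solid block, a half-space void with flat interface
#' (`slab_void`), axis-aligned cylindrical void channels (`cyl_channel`), a
#' spherical void pore (`spherical_pore`), a void layer normal to the loading
#' axis (`laminate_series`) and solid walls aligned with it
#' (`laminate_parallel`).
#'
#' @param kind Fixture name (see Details).
#' @param n Grid dimensions in voxels (length 1 or 3).
#' @param spacing Voxel edge, mm.
#' @param ... Shape parameters: `radius` (mm; may be a vector for several
#'   channels), `centers` (matrix of channel axis positions in mm, columns
#'   x/y, for `cyl_channel`), `center` (mm, `spherical_pore`), `solid_frac`
#'   (laminates and `slab_void`).
#' @return A [voxel_grid()].
#' @export
make_fixture <- function(kind = c("solid_block", "slab_void", "cyl_channel",
                                  "spherical_pore", "laminate_series",
                                  "laminate_parallel"),
                         n = 48, spacing = 0.02, ...) {
  kind <- match.arg(kind)
  n <- as.integer(rep(n, length.out = 3))
  args <- list(...)
  ext <- n * spacing
  cx <- .axis_centres(n[1], spacing, 0)
  cy <- .axis_centres(n[2], spacing, 0)
  cz <- .axis_centres(n[3], spacing, 0)
  # analytic signed distance to the shape surface (positive in solid), used as
  # the level-set seed; occupancy is its non-negative set
  seed <- switch(kind,
    solid_block = array(1, dim = n),
    slab_void = {
      sf <- args$solid_frac %||% 0.5
      array(rep(sf * ext[3] - cz, each = n[1] * n[2]), dim = n)
    },
    cyl_channel = {
      radius <- args$radius %||% 0.2
      centers <- args$centers
      if (is.null(centers)) centers <- matrix(ext[1:2] / 2, ncol = 2)
      if (!is.matrix(centers)) centers <- matrix(centers, ncol = 2)
      radius <- rep(radius, length.out = nrow(centers))
      if (any(radius <= 0)) stop("channel radius must be > 0")
      if (any(centers[, 1] + radius > ext[1] | centers[, 1] - radius < 0 |
              centers[, 2] + radius > ext[2] | centers[, 2] - radius < 0))
        stop("channel does not fit inside the grid")
      s2d <- matrix(Inf, n[1], n[2])
      for (ch in seq_len(nrow(centers))) {
        d <- sqrt(outer((cx - centers[ch, 1])^2, (cy - centers[ch, 2])^2, "+"))
        s2d <- pmin(s2d, d - radius[ch])
      }
      array(rep(s2d, times = n[3]), dim = n)
    },
    spherical_pore = {
      radius <- args$radius %||% (min(ext) / 4)
      center <- args$center %||% (ext / 2)
      if (any(center + radius > ext) || any(center - radius < 0))
        stop("sphere does not fit inside the grid")
      d2 <- outer(outer((cx - center[1])^2, (cy - center[2])^2, "+"),
                  (cz - center[3])^2, "+")
      array(sqrt(d2) - radius, dim = n)
    },
    laminate_series = {
      sf <- args$solid_frac %||% 0.5
      nvoid <- n[3] - round(sf * n[3])
      k0 <- floor((n[3] - nvoid) / 2)
      z1 <- k0 * spacing
      z2 <- (k0 + nvoid) * spacing
      sz <- if (nvoid > 0) pmax(z1 - cz, cz - z2) else rep(1, n[3])
      array(rep(sz, each = n[1] * n[2]), dim = n)
    },
    laminate_parallel = {
      sf <- args$solid_frac %||% 0.5
      nsolid <- round(sf * n[1])
      x0 <- nsolid * spacing
      array(rep(x0 - cx, times = n[2] * n[3]), dim = n)
    })
  g <- voxel_grid(seed >= 0, spacing)
  g$phi_seed <- seed
  g$phi_exact <- TRUE   # the seed is already a signed distance
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
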