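#' Pore diameter limits
#'
#' The admissible pore-diameter window for capillary-fed scaffolds: pores must
#' be at least 100 um wide for capillary infiltration and at most 400 um so no
#' surface lies beyond the ~200 um oxygen/nutrient diffusion limit from the
#' capillary running along the pore centreline.
#'
#' @param d_lo Minimum pore diameter, um (default 100).
#' @param d_hi Maximum pore diameter, um (default 400).
#' @return An object of class `pore_limits`.
#' @export
pore_limits <- function(d_lo = 100, d_hi = 400) {
  if (!(d_lo > 0 && d_hi > d_lo)) stop("need 0 < d_lo < d_hi")
  structure(list(d_lo = d_lo, d_hi = d_hi), class = "pore_limits")
}

#' Medial-axis skeleton of the void network
#'
#' Homotopic thinning of the void phase ordered by increasing Euclidean
#' distance to the solid: simple points are removed until only a thin,
#' topology-preserving medial skeleton remains (26-connectivity for the void,
#' 6-connectivity for its complement; curve endpoints are preserved). By
#' default only the largest connected void component is skeletonised -- a
#' capillary cannot reach voids that are sealed off -- and the number of
#' disconnected components is reported alongside.
#'
#' @param grid A [voxel_grid()] with at least one void voxel.
#' @param components `"largest"` (default) or `"all"`.
#' @return List with `skeleton` (logical array), `void_components` (count of
#'   26-connected void components) and `skeleton_voxel_count`.
#' @export
void_skeleton <- function(grid, components = c("largest", "all")) {
  stopifnot(inherits(grid, "voxel_grid"))
  components <- match.arg(components)
  void <- !grid$occupancy
  if (!any(void)) stop("no void: grid is entirely solid")
  d <- dim(void)
  ncomp <- .count_components_cpp(as.logical(void), d, 26L)
  mask <- as.logical(void)
  if (components == "largest" && ncomp > 1)
    mask <- .largest_component_cpp(mask, d, 26L)
  skel <- .thin_skeleton_cpp(mask, d)
  list(skeleton = array(skel, dim = d),
       void_components = ncomp,
       skeleton_voxel_count = sum(skel))
}

# retained skeleton after boundary exclusion and spur pruning
.retained_skeleton <- function(skel, boundary_margin = 2, min_branch = 3) {
  d <- dim(skel)
  if (boundary_margin > 0) {
    idx <- which(skel, arr.ind = TRUE)
    keep <- idx[, 1] > boundary_margin & idx[, 1] <= d[1] - boundary_margin &
            idx[, 2] > boundary_margin & idx[, 2] <= d[2] - boundary_margin &
            idx[, 3] > boundary_margin & idx[, 3] <= d[3] - boundary_margin
    skel <- array(FALSE, dim = d)
    skel[idx[keep, , drop = FALSE]] <- TRUE
  }
  if (min_branch > 0)
    skel <- array(.prune_skeleton_cpp(as.logical(skel), d, as.integer(min_branch)),
                  dim = d)
  skel
}

#' Minimum and maximum pore diameters
#'
#' Computes the Euclidean distance from every retained medial-skeleton voxel
#' to the nearest solid voxel; twice the smallest and largest such distances
#' are the diameters of the smallest and largest virtual spheres inscribed in
#' the void network. Skeleton voxels within `boundary_margin` voxels of the
#' domain boundary are excluded and terminal branches shorter than
#' `min_branch` voxels are pruned first (raw thinning produces boundary and
#' spur artefacts that would otherwise drive the minimum to spurious values).
#' Distances are reduced by half a voxel spacing to approximate the solid
#' surface rather than the nearest solid voxel centre
#' (`surface_correction = FALSE` disables this).
#'
#' @param grid A [voxel_grid()]; for TPMS scaffolds use a 3 x 3 x 3 tiling so
#'   the largest and smallest voids are represented.
#' @param limits A [pore_limits()] (carried through to the result).
#' @param components Passed to [void_skeleton()].
#' @param boundary_margin,min_branch Skeleton retention parameters (voxels).
#' @param surface_correction Subtract half a spacing from radii (default TRUE).
#' @return List of class `pore_size_result`: `d_min_um`, `d_max_um`,
#'   `skeleton_voxel_count`, `void_components`, `limits`.
#' @export
pore_diameters <- function(grid, limits = pore_limits(),
                           components = "largest", boundary_margin = 2,
                           min_branch = 3, surface_correction = TRUE) {
  sk <- void_skeleton(grid, components = components)
  ret <- .retained_skeleton(sk$skeleton, boundary_margin, min_branch)
  if (!any(ret))
    stop("no skeleton voxels retained after boundary exclusion and pruning")
  d <- dim(grid$occupancy)
  h <- grid$spacing
  dist_vox <- sqrt(.edt_sq_cpp(as.logical(grid$occupancy), d))
  r_mm <- dist_vox[which(ret)] * h - if (surface_correction) h / 2 else 0
  r_mm <- pmax(r_mm, h / 2)
  structure(list(d_min_um = 2000 * min(r_mm), d_max_um = 2000 * max(r_mm),
                 skeleton_voxel_count = sum(ret),
                 void_components = sk$void_components, limits = limits),
            class = "pore_size_result")
}

#' @export
print.pore_size_result <- function(x, ...) {
  cat(sprintf("pore sizes: d_min %.1f um, d_max %.1f um (%d skeleton voxels)\n",
              x$d_min_um, x$d_max_um, x$skeleton_voxel_count))
  invisible(x)
}

#' Pore-size sweep over volume fraction
#'
#' Runs [pore_diameters()] on a tiled scaffold for each volume fraction in the
#' sweep. Each scaffold is voxelised with a threshold calibrated at the same
#' resolution used for the analysis.
#'
#' @param tpms_type One of [tpms_types()].
#' @param vf_sweep Ascending volume fractions within `[0.2, 0.9]`.
#' @param resolution Voxels per unit cell (default 60).
#' @param limits A [pore_limits()].
#' @param tiling Cells per axis (default 3).
#' @param cell_size Unit-cell edge, mm.
#' @param ... Passed to [pore_diameters()].
#' @return data.frame with columns `type`, `vf`, `d_min_um`, `d_max_um`.
#' @export
pore_sweep <- function(tpms_type, vf_sweep, resolution = 60,
                       limits = pore_limits(), tiling = 3, cell_size = 1, ...) {
  rows <- lapply(vf_sweep, function(vf) {
    res <- .cached("pore", tpms_type, vf, resolution, tiling, cell_size,
                   list(...), compute = function() {
      t <- calibrate_t(tpms_type, vf, resolution = resolution,
                       cell_size = cell_size)
      spec <- scaffold_spec(tpms_type, t, cell_size = cell_size,
                            repetitions = tiling)
      grid <- voxelize(spec, resolution)
      pore_diameters(grid, limits = limits, ...)
    })
    data.frame(type = tpms_type, vf = vf,
               d_min_um = res$d_min_um, d_max_um = res$d_max_um)
  })
  do.call(rbind, rows)
}

# linear interpolation of the vf at which y crosses y0 (first crossing,
# scanning in the direction of increasing vf); NA if no crossing
.crossing_vf <- function(vf, y, y0, rising) {
  for (i in seq_len(length(vf) - 1)) {
    y1 <- y[i]; y2 <- y[i + 1]
    hit <- if (rising) (y1 < y0 && y2 >= y0) else (y1 >= y0 && y2 < y0)
    if (hit) return(vf[i] + (y0 - y1) / (y2 - y1) * (vf[i + 1] - vf[i]))
  }
  NA_real_
}

#' Volume-fraction window satisfying the pore constraints
#'
#' Sweeps pore sizes over volume fraction and returns the contiguous interval
#' where the largest pore is at most `d_hi` and the smallest pore at least
#' `d_lo`. Both pore diameters decrease as material is added, so the window
#' lower edge is the `d_max = d_hi` crossing and the upper edge the
#' `d_min = d_lo` crossing, with crossings located by linear interpolation
#' between sweep points. An empty window flags the type as discarded. When
#' `early_exclude` is set and the largest pore still exceeds `d_hi` at the
#' densest sweep point (pore sizes shrink with volume fraction), the type is
#' excluded without evaluating the rest of the sweep.
#'
#' @inheritParams pore_sweep
#' @param early_exclude Logical (default TRUE).
#' @return List of class `vf_window`: `lo`, `hi` (NA when empty), `empty`,
#'   `reason`, `sweep` (the pore-size table actually computed).
#' @export
pore_window <- function(tpms_type, vf_sweep = seq(0.2, 0.9, by = 0.05),
                        resolution = 60, limits = pore_limits(), tiling = 3,
                        cell_size = 1, early_exclude = TRUE, ...) {
  stopifnot(!is.unsorted(vf_sweep))
  if (any(vf_sweep < 0.2 - 1e-9 | vf_sweep > 0.9 + 1e-9))
    stop("vf_sweep must lie within [0.2, 0.9]")
  if (early_exclude) {
    top <- pore_sweep(tpms_type, vf_sweep[length(vf_sweep)], resolution,
                      limits, tiling, cell_size, ...)
    if (top$d_max_um > limits$d_hi) {
      return(structure(list(
        lo = NA_real_, hi = NA_real_, empty = TRUE,
        reason = sprintf("max pore %.0f um > %.0f um at VF %.2f (largest pore exceeds the limit at every VF)",
                         top$d_max_um, limits$d_hi, top$vf),
        sweep = top), class = "vf_window"))
    }
  }
  sw <- pore_sweep(tpms_type, vf_sweep, resolution, limits, tiling,
                   cell_size, ...)
  ok <- sw$d_max_um <= limits$d_hi & sw$d_min_um >= limits$d_lo
  if (!any(ok)) {
    reason <- if (all(sw$d_max_um > limits$d_hi))
      sprintf("max pore > %.0f um at all VF", limits$d_hi)
    else sprintf("no VF satisfies %g-%g um pore limits", limits$d_lo, limits$d_hi)
    return(structure(list(lo = NA_real_, hi = NA_real_, empty = TRUE,
                          reason = reason, sweep = sw), class = "vf_window"))
  }
  lo <- .crossing_vf(sw$vf, sw$d_max_um, limits$d_hi, rising = FALSE)
  if (is.na(lo)) lo <- min(sw$vf[ok])
  hi <- .crossing_vf(sw$vf, sw$d_min_um, limits$d_lo, rising = FALSE)
  if (is.na(hi)) hi <- max(sw$vf[ok])
  structure(list(lo = lo, hi = hi, empty = FALSE, reason = NA_character_,
                 sweep = sw), class = "vf_window")
}

#' @export
print.vf_window <- function(x, ...) {
  if (x$empty) cat("VF window: empty (", x$reason, ")\n", sep = "")
  else cat(sprintf("VF window: [%.3f, %.3f]\n", x$lo, x$hi))
  invisible(x)
}
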