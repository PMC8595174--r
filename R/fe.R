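#' Uniaxial-compression FE problem on a voxel grid
#'
#' Describes the homogenisation test: trilinear 8-node hexahedral elements on
#' the solid voxels, the bottom face fixed in the loading (z) direction, the
#' top face given a uniform compressive displacement, lateral faces
#' traction-free. Solid clusters not connected to both loading faces carry no
#' load and are removed before assembly.
#'
#' @param grid A [voxel_grid()].
#' @param E Material modulus, Pa (default 1.8e9; E* is independent of it).
#' @param nu Poisson ratio in (0, 0.5) (default 0.3).
#' @param applied_strain Compressive strain magnitude (default 1e-3; the
#'   problem is linear, so E* is independent of it).
#' @return Object of class `fe_problem`.
#' @export
fe_problem <- function(grid, E = 1.8e9, nu = 0.3, applied_strain = 1e-3) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!(nu > 0 && nu < 0.5)) stop("poisson_ratio must lie in (0, 0.5)")
  if (applied_strain <= 0) stop("applied_strain must be > 0")
  structure(list(grid = grid, E = E, nu = nu,
                 applied_strain = applied_strain),
            class = "fe_problem")
}

# 24 x 24 stiffness matrix of a cubic trilinear hexahedron, edge h,
# unit modulus, Poisson ratio nu; 2x2x2 Gauss quadrature.
.hex8_ke <- function(h, nu) {
  # local node coordinates, matching voxel corner ordering used in assembly
  xi <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
              c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  gp <- 1 / sqrt(3)
  pts <- as.matrix(expand.grid(c(-gp, gp), c(-gp, gp), c(-gp, gp)))
  Ke <- matrix(0, 24, 24)
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    # dN/dxi (8 x 3), then dN/dx = dN/dxi * 2/h
    dN <- matrix(0, 8, 3)
    for (a in 1:8) {
      dN[a, 1] <- 0.125 * xi[a, 1] * (1 + p[2] * xi[a, 2]) * (1 + p[3] * xi[a, 3])
      dN[a, 2] <- 0.125 * xi[a, 2] * (1 + p[1] * xi[a, 1]) * (1 + p[3] * xi[a, 3])
      dN[a, 3] <- 0.125 * xi[a, 3] * (1 + p[1] * xi[a, 1]) * (1 + p[2] * xi[a, 2])
    }
    dN <- dN * (2 / h)
    B <- matrix(0, 6, 24)
    for (a in 1:8) {
      c0 <- 3 * (a - 1)
      B[1, c0 + 1] <- dN[a, 1]
      B[2, c0 + 2] <- dN[a, 2]
      B[3, c0 + 3] <- dN[a, 3]
      B[4, c0 + 1] <- dN[a, 2]; B[4, c0 + 2] <- dN[a, 1]
      B[5, c0 + 2] <- dN[a, 3]; B[5, c0 + 3] <- dN[a, 2]
      B[6, c0 + 1] <- dN[a, 3]; B[6, c0 + 3] <- dN[a, 1]
    }
    Ke <- Ke + t(B) %*% D %*% B * (h / 2)^3
  }
  (Ke + t(Ke)) / 2
}

# keep only solid clusters connected (6-conn) to both z faces
.percolating_solid <- function(occ) {
  d <- dim(occ)
  lab <- array(.label_components_cpp(as.logical(occ), d, 6L), dim = d)
  bottom <- unique(as.vector(lab[, , 1]))
  top <- unique(as.vector(lab[, , d[3]]))
  keep <- setdiff(intersect(bottom, top), 0L)
  if (length(keep) == 0) return(array(FALSE, dim = d))
  array(lab %in% keep, dim = d)
}

#' Relative modulus by voxel finite elements
#'
#' Assembles trilinear hexahedral elements on the solid voxels, applies a
#' uniform compressive displacement to the top face (bottom face fixed in z,
#' lateral faces free; in-plane rigid-body modes are suppressed by a
#' negligible diagonal regularisation), and returns
#' `E* = (reaction force / cross-section area / strain) / E`. The full
#' bounding cross-section is used, so `E*` is the effective modulus of the
#' homogenised block.
#'
#' @param problem An [fe_problem()].
#' @return Relative modulus `E*` (0 when the solid does not percolate between
#'   the loading faces, with a warning). Attribute `diag` carries solve
#'   diagnostics.
#' @export
voxel_modulus <- function(problem) {
  stopifnot(inherits(problem, "fe_problem"))
  occ <- .percolating_solid(problem$grid$occupancy)
  d <- dim(occ)
  if (!any(occ)) {
    warning("solid phase does not percolate between the loading faces; E* = 0")
    return(structure(0, diag = list(percolating = FALSE)))
  }
  h <- problem$grid$spacing
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  nnx <- nx + 1L; nny <- ny + 1L; nnz <- nz + 1L
  nid <- function(i, j, k) 1L + i + nnx * (j + nny * k)  # 0-based corners

  vox <- which(occ, arr.ind = TRUE)  # 1-based voxel indices
  i0 <- vox[, 1] - 1L; j0 <- vox[, 2] - 1L; k0 <- vox[, 3] - 1L
  corner <- cbind(nid(i0,      j0,      k0),
                  nid(i0 + 1L, j0,      k0),
                  nid(i0 + 1L, j0 + 1L, k0),
                  nid(i0,      j0 + 1L, k0),
                  nid(i0,      j0,      k0 + 1L),
                  nid(i0 + 1L, j0,      k0 + 1L),
                  nid(i0 + 1L, j0 + 1L, k0 + 1L),
                  nid(i0,      j0 + 1L, k0 + 1L))
  ne <- nrow(corner)
  edof <- matrix(0L, ne, 24)
  for (a in 1:8) {
    edof[, 3 * a - 2] <- 3L * corner[, a] - 2L
    edof[, 3 * a - 1] <- 3L * corner[, a] - 1L
    edof[, 3 * a]     <- 3L * corner[, a]
  }
  Ke <- .hex8_ke(h, problem$nu)
  ii <- as.vector(edof[, rep(1:24, times = 24)])
  jj <- as.vector(edof[, rep(1:24, each = 24)])
  xx <- rep(as.vector(Ke), each = ne)
  ndof <- 3L * nnx * nny * nnz
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  rm(ii, jj, xx)

  # prescribed dofs: uz on the top and bottom faces of the attached nodes
  attached <- sort(unique(as.vector(corner)))
  kk <- (attached - 1L) %/% (nnx * nny)  # node layer, 0-based
  bottom_n <- attached[kk == 0L]
  top_n <- attached[kk == nz]
  Lz <- nz * h
  delta <- problem$applied_strain * Lz
  pres <- c(3L * bottom_n, 3L * top_n)
  pval <- c(rep(0, length(bottom_n)), rep(-delta, length(top_n)))

  free <- setdiff(seq_len(ndof), pres)
  Kff <- K[free, free, drop = FALSE]
  # negligible ridge: suppresses in-plane rigid modes and unattached nodes
  ridge <- 1e-8 * mean(Matrix::diag(K)[Matrix::diag(K) > 0])
  Kff <- Kff + ridge * Matrix::Diagonal(length(free))
  rhs <- -K[free, pres, drop = FALSE] %*% pval
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                         super = TRUE)
  uf <- Matrix::solve(ch, rhs)

  u <- numeric(ndof)
  u[free] <- as.numeric(uf)
  u[pres] <- pval
  r <- as.numeric(K %*% u)
  F_top <- abs(sum(r[3L * top_n]))
  A <- nx * ny * h^2
  E_star <- F_top / (A * problem$applied_strain)  # unit-modulus material
  structure(E_star,
            diag = list(percolating = TRUE, n_elements = ne,
                        n_dof = length(free), reaction_N = F_top,
                        ridge = ridge))
}

#' FE sweep over volume fraction and Gibson-Ashby fit
#'
#' Runs [voxel_modulus()] on one unit cell per volume fraction (threshold
#' calibrated at the analysis resolution) and fits the resulting moduli with
#' [fit_scaling_law()].
#'
#' @param tpms_type One of [tpms_types()].
#' @param vf_sweep Volume fractions within `[0.2, 0.9]`.
#' @param resolution Voxels per cell (default 32).
#' @param cell_size Unit-cell edge, mm.
#' @param nu Poisson ratio.
#' @param repetitions Cells per axis in the FE domain (default 1).
#' @return The fitted [scaling_law()]; attribute `data` holds the raw
#'   `vf`/`E_star` table.
#' @export
sweep_and_fit <- function(tpms_type, vf_sweep, resolution = 32, cell_size = 1,
                          nu = 0.3, repetitions = 1L) {
  stopifnot(all(vf_sweep >= 0.2 & vf_sweep <= 0.9))
  es <- vapply(vf_sweep, function(vf) {
    .cached("fe", tpms_type, vf, resolution, cell_size, nu, repetitions,
            compute = function() {
      t <- calibrate_t(tpms_type, vf, resolution = resolution,
                       cell_size = cell_size)
      grid <- voxelize(scaffold_spec(tpms_type, t, cell_size, repetitions),
                       resolution)
      as.numeric(voxel_modulus(fe_problem(grid, nu = nu)))
    })
  }, numeric(1))
  law <- fit_scaling_law(vf_sweep, es, tpms_type)
  attr(law, "data") <- data.frame(type = tpms_type, vf = vf_sweep, E_star = es)
  law
}
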