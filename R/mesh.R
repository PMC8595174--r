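#' Signed distance field of a voxel grid
#'
#' Exact Euclidean distance to the solid/void interface, positive inside the
#' solid phase. The interface is placed halfway between adjacent solid and
#' void voxel centres, so a solid voxel touching the interface carries
#' `phi = spacing / 2`.
#'
#' @param grid A [voxel_grid()].
#' @return Numeric 3-D array of distances in mm.
#' @export
signed_distance <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- grid$occupancy
  d <- dim(occ)
  h <- grid$spacing
  if (all(occ) || !any(occ))
    stop("grid must contain both solid and void voxels")
  if (isTRUE(grid$phi_exact)) return(grid$phi_seed)
  if (!is.null(grid$phi_seed))   # rebuild from sub-voxel crossings of the seed
    return(array(.fmm_redistance_cpp(as.numeric(grid$phi_seed), d, h,
                                     FALSE, Inf), dim = d))
  d_solid <- sqrt(.edt_sq_cpp(as.logical(occ), d))
  d_void <- sqrt(.edt_sq_cpp(!as.logical(occ), d))
  phi <- ifelse(as.logical(occ), d_void * h - h / 2, -(d_solid * h - h / 2))
  array(phi, dim = d)
}

#' Export a triangulated scaffold surface as STL
#'
#' Builds a signed distance field from the occupancy grid and triangulates its
#' zero level by marching tetrahedra, writing a binary STL with vertex
#' coordinates in mm. The mesh is watertight wherever the interface does not
#' intersect the grid boundary.
#'
#' @param grid A [voxel_grid()] containing both phases.
#' @param path Output file path.
#' @return Invisibly, the triangle matrix (one row per triangle, columns
#'   `x1,y1,z1,...,z3`).
#' @export
export_surface <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  occ <- grid$occupancy
  if (all(occ) || !any(occ))
    stop("no surface: grid is entirely ", if (all(occ)) "solid" else "void")
  phi <- signed_distance(grid)
  h <- grid$spacing
  origin <- grid$origin + h / 2  # field samples sit at voxel centres
  tris <- .march_tets_cpp(as.numeric(phi), dim(phi), h, origin, 0)
  if (nrow(tris) == 0) stop("no surface: isosurface is empty")
  write_stl(tris, path)
  invisible(tris)
}

#' Write a triangle soup to binary STL
#'
#' @param triangles Matrix with 9 columns (three xyz vertices per row).
#' @param path Output path.
#' @export
write_stl <- function(triangles, path) {
  stopifnot(is.matrix(triangles), ncol(triangles) == 9)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- raw(80)
  writeBin(header, con)
  writeBin(as.integer(nrow(triangles)), con, size = 4, endian = "little")
  v1 <- triangles[, 1:3, drop = FALSE]
  v2 <- triangles[, 4:6, drop = FALSE]
  v3 <- triangles[, 7:9, drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  rec <- t(cbind(nrm, v1, v2, v3))  # 12 floats per triangle
  for (i in seq_len(ncol(rec))) {
    writeBin(as.numeric(rec[, i]), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a binary STL file
#'
#' @param path STL path (binary format).
#' @return Matrix with 9 columns, one triangle per row.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(ntri) || ntri < 0) stop("corrupt STL file: ", path)
  out <- matrix(0, ntri, 9)
  for (i in seq_len(ntri)) {
    rec <- readBin(con, "numeric", 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("truncated STL file: ", path)
    invisible(readBin(con, "raw", 2))
    out[i, ] <- rec[4:12]
  }
  out
}

#' Total area of a triangle mesh
#'
#' @param triangles Matrix with 9 columns (as returned by [read_stl()]).
#' @return Area in mm^2.
#' @export
mesh_area <- function(triangles) {
  e1 <- triangles[, 4:6, drop = FALSE] - triangles[, 1:3, drop = FALSE]
  e2 <- triangles[, 7:9, drop = FALSE] - triangles[, 1:3, drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(nrm^2))) / 2
}
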