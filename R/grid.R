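#' Define a regular voxel grid
#'
#' A grid is the shared sampling lattice of every volume in an analysis:
#' an integer shape, strictly positive voxel sizes in mm, and an affine
#' mapping 0-based voxel indices to world coordinates in mm. By default the
#' grid is centred on the world origin (the stimulation target), so a
#' 48x48x48 grid at 0.5 mm spans a 24 mm cube around the target.
#'
#' @param shape integer length-3 vector of voxel counts per axis.
#' @param voxel_size_mm positive voxel edge lengths in mm (scalar recycled).
#' @param origin_mm world coordinates (mm) of the centre of voxel (0,0,0);
#'   default centres the grid on the origin.
#' @return An object of class `voxel_grid` with fields `shape`,
#'   `voxel_size_mm`, `origin_mm` and the 4x4 `affine`.
#' @export
voxel_grid <- function(shape = c(48L, 48L, 48L),
                       voxel_size_mm = c(0.5, 0.5, 0.5),
                       origin_mm = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be three positive integers")
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three strictly positive numbers")
  if (is.null(origin_mm)) origin_mm <- -(shape - 1L) * voxel_size_mm / 2
  origin_mm <- as.numeric(origin_mm)
  affine <- diag(4)
  affine[cbind(1:3, 1:3)] <- voxel_size_mm
  affine[1:3, 4] <- origin_mm
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         origin_mm = origin_mm, affine = affine),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(x$shape, collapse = " x "),
      "voxels,", paste(x$voxel_size_mm, collapse = " x "),
      "mm, origin (", paste(format(x$origin_mm), collapse = ", "), ") mm\n")
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-8) {
  identical(a$shape, b$shape) &&
    max(abs(a$affine - b$affine)) <= tol
}

stop_grid_mismatch <- function(a, b, what = "volumes") {
  stop(sprintf("grid mismatch between %s: shape (%s) vs (%s)",
               what, paste(a$shape, collapse = ","),
               paste(b$shape, collapse = ",")))
}

#' Axis coordinates of voxel centres
#'
#' @param grid a `voxel_grid`.
#' @return list with numeric vectors `x`, `y`, `z` of voxel-centre world
#'   coordinates (mm) along each axis.
#' @export
grid_axes <- function(grid) {
  list(
    x = grid$origin_mm[1] + (seq_len(grid$shape[1]) - 1) * grid$voxel_size_mm[1],
    y = grid$origin_mm[2] + (seq_len(grid$shape[2]) - 1) * grid$voxel_size_mm[2],
    z = grid$origin_mm[3] + (seq_len(grid$shape[3]) - 1) * grid$voxel_size_mm[3]
  )
}

#' World coordinates (mm) of voxels given 1-based linear indices
#'
#' @param grid a `voxel_grid`.
#' @param idx integer vector of 1-based linear voxel indices (column-major).
#' @return numeric matrix with one row per index and columns x, y, z (mm).
#' @export
voxel_centers_mm <- function(grid, idx = seq_len(prod(grid$shape))) {
  ind <- arrayInd(idx, grid$shape)
  sweep(sweep(ind - 1, 2, grid$voxel_size_mm, `*`), 2, grid$origin_mm, `+`)
}

#' Volume of one voxel in mm^3
#' @param grid a `voxel_grid`.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size_mm)

# squared distances (mm^2) from every voxel centre to a world point
grid_dist2 <- function(grid, point_mm) {
  ax <- grid_axes(grid)
  dx2 <- (ax$x - point_mm[1])^2
  dy2 <- (ax$y - point_mm[2])^2
  dz2 <- (ax$z - point_mm[3])^2
  sh <- grid$shape
  array(dx2, dim = sh) +
    array(rep(dy2, each = sh[1]), dim = sh) +
    array(rep(dz2, each = sh[1] * sh[2]), dim = sh)
}
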