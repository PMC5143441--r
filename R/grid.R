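#' Voxel grid geometry
#'
#' Defines the regular 3D lattice on which acoustic models and pressure
#' volumes live.  The beam propagation axis is fixed as +z.  Voxel centers
#' are at `origin + (i*dx, j*dy, k*dz)` with 0-based indices, so `origin`
#' is the center of voxel `[1,1,1]`.
#'
#' @param dims integer vector `(nx, ny, nz)`, all >= 1.
#' @param spacing numeric vector `(dx, dy, dz)` in meters, all > 0.
#' @param origin numeric vector, physical position (m) of the first voxel
#'   center.  Default centers the grid laterally on `x = y = 0` with the
#'   first slice at `z = 0`.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, spacing, origin = NULL) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be three integers >= 1", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive lengths (m)", call. = FALSE)
  if (is.null(origin)) {
    origin <- c(-(dims[1] - 1) * spacing[1] / 2,
                -(dims[2] - 1) * spacing[2] / 2,
                0)
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite coordinates (m)", call. = FALSE)
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              1e3 * x$spacing[1], 1e3 * x$spacing[2], 1e3 * x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm; extent %.4g x %.4g x %.4g mm\n",
              1e3 * x$origin[1], 1e3 * x$origin[2], 1e3 * x$origin[3],
              1e3 * x$dims[1] * x$spacing[1], 1e3 * x$dims[2] * x$spacing[2],
              1e3 * x$dims[3] * x$spacing[3]))
  invisible(x)
}

#' Voxel-center coordinates along one grid axis
#'
#' @param grid a [voxel_grid()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of physical coordinates (m).
#' @export
grid_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "voxel_grid"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 1L) * grid$spacing[axis]
}

#' Nearest voxel index for a physical point
#'
#' @param grid a [voxel_grid()].
#' @param point numeric `(x, y, z)` in meters.
#' @return integer vector `(i, j, k)` (1-based), clamped to the grid.
#' @export
nearest_voxel <- function(grid, point) {
  stopifnot(inherits(grid, "voxel_grid"), length(point) == 3L)
  idx <- round((as.numeric(point) - grid$origin) / grid$spacing) + 1L
  pmin(pmax(as.integer(idx), 1L), grid$dims)
}

#' Physical coordinates of a voxel index
#'
#' @param grid a [voxel_grid()].
#' @param idx integer `(i, j, k)`, 1-based.
#' @return numeric `(x, y, z)` in meters.
#' @export
voxel_center <- function(grid, idx) {
  stopifnot(inherits(grid, "voxel_grid"), length(idx) == 3L)
  grid$origin + (as.numeric(idx) - 1) * grid$spacing
}

grids_equal <- function(a, b, tol = 1e-12) {
  all(a$dims == b$dims) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
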