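#' Regular 2-D voxel grid over the sample
#'
#' The square sample is subdivided into `nx` by `ny` square voxels of side
#' `dx = side_x / nx`. The sample is centered at the origin unless another
#' `origin` (lower-left corner) is given. Voxel centers sit at
#' `origin + ((i + 1/2) dx, (j + 1/2) dx)` for 0-based `i`, `j`, and the
#' concentration vector is flattened row-major in x first:
#' `k = i + nx * j` (0-based; R vectors are indexed at `k + 1`).
#'
#' @param nx,ny Number of voxels along x and y.
#' @param side_x,side_y Sample side lengths (m). Default 0.08 m square.
#' @param origin Lower-left corner (m); default centers the sample at 0.
#' @return List of class `grid2d` with fields `nx, ny, dx, origin, n`.
#' @examples
#' g <- grid_2d(31, 31)
#' g$n           # 961 states
#' g$dx          # 0.08 / 31
#' @export
grid_2d <- function(nx = 31, ny = 31, side_x = 0.08, side_y = side_x,
                    origin = c(-side_x / 2, -side_y / 2)) {
  stopifnot(nx >= 1, ny >= 1, side_x > 0, side_y > 0)
  dx <- side_x / nx
  dy <- side_y / ny
  if (abs(dx - dy) > 1e-12 * dx) {
    stop("voxels must be square: side_x/nx must equal side_y/ny",
         call. = FALSE)
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), dx = dx,
         origin = as.numeric(origin), n = as.integer(nx * ny)),
    class = "grid2d"
  )
}

#' @export
print.grid2d <- function(x, ...) {
  cat(sprintf("<grid2d> %d x %d voxels, dx = %.4g m, origin (%.3g, %.3g) m\n",
              x$nx, x$ny, x$dx, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Voxel center table
#'
#' @param grid A [grid_2d()] object.
#' @return Tibble with one row per voxel: 0-based indices `i`, `j`, the
#'   flat index `k = i + nx j` (0-based), and center coordinates `x`, `y`
#'   (m), ordered by `k`.
#' @export
voxel_centers <- function(grid) {
  i <- rep(seq_len(grid$nx) - 1L, times = grid$ny)
  j <- rep(seq_len(grid$ny) - 1L, each = grid$nx)
  tibble::tibble(
    i = i, j = j, k = i + grid$nx * j,
    x = grid$origin[1] + (i + 0.5) * grid$dx,
    y = grid$origin[2] + (j + 0.5) * grid$dx
  )
}

#' Flat voxel index of the voxel containing a point
#'
#' @param grid A [grid_2d()] object.
#' @param x,y Point coordinates (m), vectorized.
#' @return Integer vector of 1-based positions into the concentration
#'   vector (i.e. `k + 1`).
#' @export
voxel_at <- function(grid, x, y) {
  i <- floor((x - grid$origin[1]) / grid$dx)
  j <- floor((y - grid$origin[2]) / grid$dx)
  if (any(i < 0 | i >= grid$nx | j < 0 | j >= grid$ny)) {
    stop("point outside the sample", call. = FALSE)
  }
  as.integer(i + grid$nx * j + 1L)
}

# Face-midpoint coordinates. x-faces separate voxels (i,j) and (i+1,j):
# (nx-1)*ny interior faces; y-faces separate (i,j) and (i,j+1): nx*(ny-1).
# Boundary faces carry zero flux and are never evaluated.
grid_faces <- function(grid) {
  dx <- grid$dx
  ox <- grid$origin[1]
  oy <- grid$origin[2]
  # x-faces: column index i (face between i and i+1), 0-based
  fx_i <- rep(seq_len(grid$nx - 1L) - 1L, times = grid$ny)
  fx_j <- rep(seq_len(grid$ny) - 1L, each = grid$nx - 1L)
  # y-faces
  fy_i <- rep(seq_len(grid$nx) - 1L, times = grid$ny - 1L)
  fy_j <- rep(seq_len(grid$ny - 1L) - 1L, each = grid$nx)
  list(
    x = list(i = fx_i, j = fx_j,
             px = ox + (fx_i + 1) * dx, py = oy + (fx_j + 0.5) * dx,
             left = fx_i + grid$nx * fx_j + 1L,
             right = fx_i + 1L + grid$nx * fx_j + 1L),
    y = list(i = fy_i, j = fy_j,
             px = ox + (fy_i + 0.5) * dx, py = oy + (fy_j + 1) * dx,
             left = fy_i + grid$nx * fy_j + 1L,
             right = fy_i + grid$nx * (fy_j + 1L) + 1L)
  )
}
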