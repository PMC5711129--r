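#' Regular 3D grid geometry
#'
#' A `grid3d` records the voxel lattice every volume, mask and vector field
#' in the package lives on: the number of voxels per axis, the voxel spacing
#' in mm, and the world coordinate (mm) of voxel index `(0, 0, 0)`. Grids are
#' axis-aligned; the world coordinate of voxel `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`. Axes are ordered `(x = LR, y = AP,
#' z = SI)` throughout.
#'
#' @param shape Integer length-3: voxels per axis, each `>= 1`.
#' @param spacing Numeric length-3: mm per voxel along each axis, all `> 0`.
#' @param origin Numeric length-3: world position (mm) of voxel `(0, 0, 0)`.
#' @return An object of class `grid3d`.
#' @examples
#' grid3d(c(64, 64, 64), spacing = c(3, 3, 3), origin = c(-94.5, -94.5, -94.5))
#' @export
grid3d <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    abort("`shape` must be three integers >= 1")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("non-positive spacing: `spacing` must be three positive numbers (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    abort("`origin` must be three finite numbers (mm)")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grid_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!grid_equal(a$grid, b$grid))
    abort(sprintf("grid mismatch: %s must share shape, spacing and origin", what))
  invisible(TRUE)
}

#' Volume of one voxel in cubic centimetres
#' @param grid A [grid3d()].
#' @return Voxel volume in cm^3.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

# World <-> continuous 0-based index coordinates (n x 3 matrices, mm).
world_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2L, grid$origin, "-"), 2L, grid$spacing, "/")
}

index_to_world <- function(grid, idx) {
  sweep(sweep(idx, 2L, grid$spacing, "*"), 2L, grid$origin, "+")
}

# n x 3 matrix of all voxel-centre world coordinates (x fastest).
voxel_centers <- function(grid) {
  ia <- index_arrays(grid$shape)
  index_to_world(grid, cbind(as.vector(ia$x), as.vector(ia$y), as.vector(ia$z)))
}

#' Scalar volume on a regular grid
#'
#' Container for CT-like images (HU), dose distributions (Gy) or unitless
#' scalar fields. Dose volumes must be non-negative; values within a small
#' numerical tolerance below zero are clamped to 0.
#'
#' @param values 3D numeric array matching `grid$shape`.
#' @param grid A [grid3d()].
#' @param unit One of `"HU"`, `"Gy"`, `"dimensionless"`.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, grid, unit = c("dimensionless", "HU", "Gy")) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    abort("`values` must be a 3D array")
  if (!identical(as.integer(dim(values)), grid$shape))
    abort("`values` dimensions do not match `grid$shape`")
  if (any(!is.finite(values)))
    abort("`values` must be finite everywhere")
  if (unit == "Gy") {
    mn <- min(values)
    if (mn < -1e-6) abort("dose volumes must be non-negative")
    if (mn < 0) values[values < 0] <- 0
  }
  structure(list(values = values, grid = grid, unit = unit),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> [%s] range [%.4g, %.4g]\n",
              x$unit, min(x$values), max(x$values)))
  print(x$grid)
  invisible(x)
}

#' Per-voxel 3D displacement field
#'
#' Displacements are in mm, stored one 3D array per component in the fixed
#' axis order (LR, AP, SI). The convention is pull-back: the vector at a
#' reference-grid position `x` points to the corresponding source-image
#' location, `x_source = x + u(x)`, so the field is directly usable for
#' resampling (see [warp_dose()]).
#'
#' @param ux,uy,uz 3D arrays (mm) matching `grid$shape`.
#' @param grid A [grid3d()].
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(ux, uy, uz, grid) {
  for (comp in list(ux, uy, uz)) {
    if (!identical(as.integer(dim(comp)), grid$shape))
      abort("displacement component dimensions do not match `grid$shape`")
    if (any(!is.finite(comp)))
      abort("displacement components must be finite everywhere")
  }
  structure(list(ux = ux, uy = uy, uz = uz, grid = grid),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf("<vector_field> |u| mean %.3g mm, max %.3g mm\n",
              mean(mag), max(mag)))
  print(x$grid)
  invisible(x)
}

#' Named binary structure mask
#'
#' @param member Logical 3D array matching `grid$shape`.
#' @param grid A [grid3d()].
#' @param name Structure label (e.g. `"GTV"`, `"liver"`, `"PTV"`).
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(member, grid, name = "structure") {
  if (!is.logical(member)) {
    if (is.numeric(member)) member <- array(member != 0, dim = dim(member))
    else abort("`member` must be a logical array")
  }
  if (!identical(as.integer(dim(member)), grid$shape))
    abort("`member` dimensions do not match `grid$shape`")
  if (any(is.na(member))) abort("`member` must not contain NA")
  structure(list(member = member, grid = grid, name = as.character(name)),
            class = "structure_mask")
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %d voxels, %.2f cc\n",
              x$name, sum(x$member), volume_cc(x)))
  print(x$grid)
  invisible(x)
}

#' Structure volume in cubic centimetres
#' @param mask A [structure_mask()].
#' @return Volume in cm^3 (member voxel count times voxel volume).
#' @export
volume_cc <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$member) * voxel_volume_cc(mask$grid)
}
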