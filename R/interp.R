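#' Trilinear sampling of a scalar volume at world coordinates
#'
#' Values at voxel centres reproduce the stored voxel values exactly;
#' interior points are convex combinations of the 8 surrounding voxels.
#' Points outside the grid are handled by `policy`: `"constant"` returns
#' `fill`, `"clamp"` extends the nearest edge value. The default policy
#' depends on the unit: dose (`Gy`) is physically ~0 outside the computed
#' grid so it uses `"constant"` with `fill = 0`; CT (`HU`) uses `"clamp"` to
#' avoid spurious air values leaking in at the border.
#'
#' @param vol A [scalar_volume()].
#' @param points Numeric `n x 3` matrix of world coordinates (mm).
#' @param policy `"auto"`, `"constant"` or `"clamp"`.
#' @param fill Out-of-grid value for the `"constant"` policy.
#' @return Numeric vector of `n` sampled values.
#' @export
sample_trilinear <- function(vol, points,
                             policy = c("auto", "constant", "clamp"),
                             fill = 0) {
  stopifnot(inherits(vol, "scalar_volume"))
  policy <- match.arg(policy)
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3L)
    abort("`points` must be an n x 3 matrix of mm coordinates")
  if (any(!is.finite(points))) abort("`points` must be finite")
  if (policy == "auto")
    policy <- if (vol$unit == "HU") "clamp" else "constant"
  idx <- world_to_index(vol$grid, points)
  cpp_trilinear(as.numeric(vol$values), vol$grid$shape, idx,
                fill, as.integer(policy == "clamp"))
}

# Sampling straight in continuous 0-based index coordinates.
sample_trilinear_index <- function(values, shape, idx, fill = 0,
                                   clamp = FALSE) {
  cpp_trilinear(as.numeric(values), as.integer(shape), idx, fill,
                as.integer(clamp))
}
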