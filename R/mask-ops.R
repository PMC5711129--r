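#' Voxel-wise boolean combination of two structure masks
#'
#' @param a,b [structure_mask()] objects on the same grid.
#' @param op `"union"`, `"intersection"` or `"difference"` (`a` and not `b`).
#' @param name Label for the result; a sensible default is derived.
#' @return A [structure_mask()].
#' @examples
#' g <- grid3d(c(10, 10, 10))
#' liver <- structure_mask(array(TRUE, c(10, 10, 10)), g, "liver")
#' m <- array(FALSE, c(10, 10, 10)); m[4:6, 4:6, 4:6] <- TRUE
#' gtv <- structure_mask(m, g, "GTV")
#' normal_liver <- mask_boolean(liver, gtv, "difference", name = "normal_liver")
#' @export
mask_boolean <- function(a, b, op = c("union", "intersection", "difference"),
                         name = NULL) {
  stopifnot(inherits(a, "structure_mask"), inherits(b, "structure_mask"))
  op <- match.arg(op)
  check_same_grid(a, b, "masks")
  member <- switch(op,
    union = a$member | b$member,
    intersection = a$member & b$member,
    difference = a$member & !b$member)
  name <- name %||% sprintf("%s_%s_%s", a$name, op, b$name)
  structure_mask(member, a$grid, name)
}

#' Isotropic margin expansion (morphological dilation) of a mask
#'
#' A voxel belongs to the output iff its centre lies within `margin_mm`
#' (Euclidean distance, mm) of some member voxel centre of the input. This
#' is how a planning margin is added around a target, e.g. PTV = ITV + 5 mm.
#'
#' @param mask A [structure_mask()].
#' @param margin_mm Margin in mm, `>= 0`. Zero returns the mask unchanged.
#' @param name Label for the result.
#' @return A [structure_mask()] containing the input.
#' @export
expand_margin <- function(mask, margin_mm, name = NULL) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!is_number(margin_mm) || margin_mm < 0)
    abort("`margin_mm` must be a single non-negative number")
  name <- name %||% sprintf("%s+%gmm", mask$name, margin_mm)
  if (margin_mm == 0)
    return(structure_mask(mask$member, mask$grid, name))
  sp <- mask$grid$spacing
  r <- floor(margin_mm / sp + 1e-9)
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 + (offs$dz * sp[3])^2
  offs <- offs[d2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  out <- array(FALSE, dim = dim(mask$member))
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_array(mask$member,
                             c(offs$dx[i], offs$dy[i], offs$dz[i]),
                             fill = FALSE)
  }
  structure_mask(out, mask$grid, name)
}

#' Centroid of a structure mask in world coordinates
#'
#' Unweighted mean of the member voxel centre positions, used e.g. to
#' measure tumour displacement between respiratory phases (see
#' [motion_vector()]).
#'
#' @param mask A non-empty [structure_mask()].
#' @return Length-3 numeric (mm), axis order (LR, AP, SI).
#' @export
mask_centroid <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  if (!any(mask$member)) abort("empty mask: centroid is undefined")
  ia <- index_arrays(mask$grid$shape)
  idx <- cbind(mean(ia$x[mask$member]), mean(ia$y[mask$member]),
               mean(ia$z[mask$member]))
  out <- as.numeric(index_to_world(mask$grid, idx))
  names(out) <- c("LR", "AP", "SI")
  out
}

#' Build ITV and PTV from the extreme-phase GTVs
#'
#' The internal target volume (ITV) combines the gross tumour volumes
#' delineated on the two extreme respiratory phases (end-expiration and
#' end-inspiration); the planning target volume (PTV) adds an isotropic
#' setup margin. The default combination is the union of the two GTVs,
#' which envelops the tumour excursion; `itv_mode = "intersection"` is
#' provided for the alternative reading of the ITV concept.
#'
#' @param gtv_exhale,gtv_inhale [structure_mask()] objects on the same grid.
#' @param margin_mm PTV margin in mm (default 5).
#' @param itv_mode `"union"` (default) or `"intersection"`.
#' @return List with elements `itv` and `ptv`.
#' @export
build_targets <- function(gtv_exhale, gtv_inhale, margin_mm = 5,
                          itv_mode = c("union", "intersection")) {
  itv_mode <- match.arg(itv_mode)
  check_same_grid(gtv_exhale, gtv_inhale, "GTV masks")
  itv <- mask_boolean(gtv_exhale, gtv_inhale, itv_mode, name = "ITV")
  ptv <- expand_margin(itv, margin_mm, name = "PTV")
  list(itv = itv, ptv = ptv)
}
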