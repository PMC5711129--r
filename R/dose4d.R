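#' Warp a dose distribution through a displacement field
#'
#' Pull-back resampling: `output(x) = dose(x + u(x))` by trilinear
#' interpolation, with 0 Gy outside the dose grid. With the field estimated
#' by registering a phase image to the reference image, this maps the dose
#' delivered in that phase onto the reference (end-expiration) anatomy so
#' that doses can be accumulated voxel by voxel.
#'
#' @param dose A [scalar_volume()] in Gy.
#' @param dvf A [vector_field()] on the same grid.
#' @return A [scalar_volume()] in Gy.
#' @export
warp_dose <- function(dose, dvf) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(dvf, "vector_field"))
  if (dose$unit != "Gy") abort("`dose` must have unit Gy")
  warp_volume(dose, dvf)
}

#' Weighted accumulation of per-phase doses
#'
#' Voxel-wise `sum_k weight_k * dose_k` over phase doses already warped to
#' the common reference grid. Weights must be non-negative and sum to 1;
#' the default is equal weighting, reflecting phase bins acquired at equally
#' spaced time intervals across the breathing cycle.
#'
#' @param doses List of [scalar_volume()] in Gy, grid-identical.
#' @param weights Optional numeric weights, one per dose.
#' @return A [scalar_volume()] in Gy.
#' @export
accumulate_dose <- function(doses, weights = NULL) {
  if (length(doses) < 1L) abort("`doses` must contain at least one volume")
  for (d in doses) {
    stopifnot(inherits(d, "scalar_volume"))
    if (d$unit != "Gy") abort("all inputs must have unit Gy")
    check_same_grid(doses[[1]], d, "phase doses")
  }
  n <- length(doses)
  weights <- weights %||% rep(1 / n, n)
  if (length(weights) != n) abort("`weights` must have one entry per dose")
  if (any(weights < 0)) abort("`weights` must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    abort("`weights` must sum to 1 (tolerance 1e-9)")
  acc <- array(0, dim = doses[[1]]$grid$shape)
  for (i in seq_len(n)) acc <- acc + weights[i] * doses[[i]]$values
  scalar_volume(acc, doses[[1]]$grid, unit = "Gy")
}

#' Named phase subsets for reduced-phase accumulation
#'
#' The standard reduced-phase schemes evaluated against the full 10-phase
#' accumulation: `p2` uses the two extreme phases (0% and 50%), `p3` the
#' 30%, 60% and 90% phases, `p5even` the even phases, `p5odd` the odd
#' phases, and `p10` all ten. Phases within a subset are equally weighted.
#'
#' @param name One of `"p2"`, `"p3"`, `"p5even"`, `"p5odd"`, `"p10"`.
#' @return An object of class `phase_subset` with `name`, `members` and
#'   equal `weights`.
#' @export
phase_subset <- function(name = c("p10", "p2", "p3", "p5even", "p5odd")) {
  name <- match.arg(name)
  members <- switch(name,
    p2 = c("0%", "50%"),
    p3 = c("30%", "60%", "90%"),
    p5even = c("0%", "20%", "40%", "60%", "80%"),
    p5odd = c("10%", "30%", "50%", "70%", "90%"),
    p10 = phase_labels(10L))
  structure(list(name = name, members = members,
                 weights = rep(1 / length(members), length(members))),
            class = "phase_subset")
}

#' Average intensity projection of the phase images
#'
#' Voxel-wise unweighted mean HU over all phases; the standard static
#' planning image derived from a 4D CT.
#'
#' @param phase_cts List of [scalar_volume()] in HU, grid-identical.
#' @return A [scalar_volume()] in HU.
#' @export
average_intensity_projection <- function(phase_cts) {
  if (length(phase_cts) < 1L) abort("`phase_cts` must not be empty")
  for (v in phase_cts) {
    stopifnot(inherits(v, "scalar_volume"))
    check_same_grid(phase_cts[[1]], v, "phase images")
  }
  acc <- array(0, dim = phase_cts[[1]]$grid$shape)
  for (v in phase_cts) acc <- acc + v$values
  scalar_volume(acc / length(phase_cts), phase_cts[[1]]$grid, unit = "HU")
}

#' Dose difference map
#'
#' Voxel-wise `a - b` for two dose distributions (Gy), e.g. a warped phase
#' dose versus the static reference dose, or a reduced-phase accumulation
#' versus the full 10-phase accumulation.
#'
#' @param a,b [scalar_volume()] objects in Gy on the same grid.
#' @return A [scalar_volume()] (Gy, signed).
#' @export
dose_difference_map <- function(a, b) {
  if (a$unit != "Gy" || b$unit != "Gy")
    abort("dose difference maps require Gy inputs")
  difference_map(a, b)
}

#' Maximum point difference within a region, as a percentage
#'
#' `100 * max(|diff|) / reference_scale` over the ROI, the summary printed
#' on dose-difference maps (e.g. maximum point dose difference inside the
#' liver, relative to the prescription dose).
#'
#' @param diff A [scalar_volume()] difference map.
#' @param roi A non-empty [structure_mask()] on the same grid.
#' @param reference_scale Normalising dose in Gy (e.g. the prescription).
#' @return Percentage (scalar).
#' @export
max_point_difference_pct <- function(diff, roi, reference_scale) {
  stopifnot(inherits(diff, "scalar_volume"), inherits(roi, "structure_mask"))
  check_same_grid(diff, roi, "difference map and ROI")
  if (!any(roi$member)) abort("empty ROI")
  if (!is_number(reference_scale) || reference_scale <= 0)
    abort("`reference_scale` must be a positive dose in Gy")
  100 * max(abs(diff$values[roi$member])) / reference_scale
}
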