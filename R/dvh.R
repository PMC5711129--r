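#' Cumulative dose-volume histogram of a structure
#'
#' Returns the cumulative DVH on a uniform dose-bin grid: `fraction[i]` is
#' the fraction of the structure volume receiving at least `dose[i]` Gy.
#' The curve starts at 1 (every voxel receives >= 0 Gy) and is
#' non-increasing; the last bin edge covers the maximum dose.
#'
#' @param dose A [scalar_volume()] in Gy.
#' @param mask A non-empty [structure_mask()] on the same grid.
#' @param bin_width Dose bin width in Gy (default 0.01).
#' @return A tibble of class `dvh_curve` with columns `dose` (bin edges,
#'   Gy) and `fraction`, plus attributes `structure`, `total_volume_cc` and
#'   `bin_width`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.01) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(mask, "structure_mask"))
  if (dose$unit != "Gy") abort("`dose` must have unit Gy")
  check_same_grid(dose, mask, "dose and mask")
  if (!any(mask$member)) abort("empty mask: DVH undefined")
  if (!is_number(bin_width) || bin_width <= 0)
    abort("`bin_width` must be positive (Gy)")
  v <- dose$values[mask$member]
  n_bins <- max(1L, ceiling(max(v) / bin_width + 1e-12)) + 1L
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  # fraction receiving >= edge; findInterval on sorted doses
  vs <- sort(v)
  below <- findInterval(edges - bin_width * 1e-9, vs)  # strictly below edge
  fraction <- 1 - below / length(vs)
  out <- tibble(dose = edges, fraction = fraction)
  attr(out, "structure") <- mask$name
  attr(out, "total_volume_cc") <- volume_cc(mask)
  attr(out, "bin_width") <- bin_width
  class(out) <- c("dvh_curve", class(out))
  out
}

#' Dose received by at least x% of the structure volume (Dx)
#'
#' The largest dose `d` such that the fraction of volume receiving at least
#' `d` is `>= x/100`, with linear interpolation between bin edges. `D2` is
#' the near-maximum dose, `D98` the near-minimum, `D95` the standard
#' prescription-coverage metric. Monotone: `x1 < x2` implies
#' `Dx1 >= Dx2`.
#'
#' @param dvh A [compute_dvh()] curve.
#' @param x_percent Volume percentage in `(0, 100]` (scalar or vector).
#' @return Dose(s) in Gy.
#' @export
dose_at_volume <- function(dvh, x_percent) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (any(x_percent <= 0 | x_percent > 100))
    abort("`x_percent` must lie in (0, 100]")
  q <- x_percent / 100
  d <- dvh$dose
  f <- dvh$fraction
  vapply(q, function(qi) {
    i <- max(which(f >= qi))        # f[1] = 1 >= qi always
    if (i == length(f)) return(d[i])
    drop_f <- f[i] - f[i + 1L]
    if (drop_f <= 0) return(d[i])
    d[i] + (f[i] - qi) / drop_f * (d[i + 1L] - d[i])
  }, numeric(1))
}

#' Mean dose over a structure
#'
#' Unweighted mean of the member-voxel doses.
#'
#' @inheritParams compute_dvh
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(mask, "structure_mask"))
  check_same_grid(dose, mask, "dose and mask")
  if (!any(mask$member)) abort("empty mask: mean dose undefined")
  mean(dose$values[mask$member])
}

#' Homogeneity index HI = D2 / D98
#'
#' Ratio of near-maximum to near-minimum dose in a structure; unity means a
#' perfectly homogeneous dose, larger values a broader DVH shoulder.
#'
#' @param d2,d98 Near-maximum and near-minimum doses in Gy (`d98 > 0`).
#' @return Dimensionless HI.
#' @export
homogeneity_index <- function(d2, d98) {
  if (any(d98 <= 0)) abort("`d98` must be positive")
  d2 / d98
}

#' Percentage ratio of two homogeneity indices
#'
#' `100 * hi_3d / hi_4d`, the conventional summary of how strongly a
#' static 3D calculation overestimates dose homogeneity relative to the 4D
#' accumulated dose (values below 100 mean the 3D plan looked more
#' homogeneous than what is delivered).
#'
#' @param hi_3d,hi_4d Homogeneity indices (`hi_4d > 0`).
#' @return Percentage.
#' @export
hi_ratio_percent <- function(hi_3d, hi_4d) {
  if (any(hi_4d <= 0)) abort("`hi_4d` must be positive")
  100 * hi_3d / hi_4d
}

#' Fractionation scheme for BED calculation
#'
#' @param n_fractions Number of fractions `n >= 1`.
#' @param alpha_beta Tissue alpha/beta ratio in Gy (10 Gy is conventional
#'   for tumour, 2 Gy for late normal-liver toxicity).
#' @return An object of class `fractionation`.
#' @export
fractionation <- function(n_fractions, alpha_beta) {
  n_fractions <- as.integer(n_fractions)
  if (n_fractions < 1L) abort("`n_fractions` must be >= 1")
  if (!is_number(alpha_beta) || alpha_beta <= 0)
    abort("`alpha_beta` must be positive (Gy)")
  structure(list(n_fractions = n_fractions, alpha_beta = alpha_beta),
            class = "fractionation")
}

#' Biologically effective dose of a uniform total dose
#'
#' `BED = n d (1 + d / (alpha/beta))` with `d = total_dose / n` the dose
#' per fraction; reduces to the physical dose as `alpha/beta -> Inf`.
#'
#' @param total_dose Total physical dose in Gy (vectorised).
#' @param n_fractions Number of fractions.
#' @param alpha_beta Tissue alpha/beta ratio (Gy).
#' @return BED in Gy.
#' @examples
#' bed(45.3, n_fractions = 6, alpha_beta = 10)
#' @export
bed <- function(total_dose, n_fractions, alpha_beta) {
  if (alpha_beta <= 0) abort("`alpha_beta` must be positive (Gy)")
  d <- total_dose / n_fractions
  n_fractions * d * (1 + d / alpha_beta)
}

#' DVH-based biologically effective dose
#'
#' Applies the BED transform bin by bin to the differential DVH: each bin's
#' total dose is split into `n` fractions, `BED_i = n d_i (1 + d_i /
#' (alpha/beta))`, and `bed_mean` is the volume-weighted mean over bins.
#' For a structure receiving a uniform dose this reduces to
#' [bed()] of that dose.
#'
#' @param dvh A [compute_dvh()] curve.
#' @param scheme A [fractionation()].
#' @return List with `bed_curve` (tibble: `bed` edges in Gy vs cumulative
#'   `fraction`) and `bed_mean` (Gy).
#' @export
bed_from_dvh <- function(dvh, scheme) {
  stopifnot(inherits(dvh, "dvh_curve"), inherits(scheme, "fractionation"))
  n <- scheme$n_fractions
  ab <- scheme$alpha_beta
  edges <- dvh$dose
  f <- dvh$fraction
  # differential volume per bin; bin i spans [edges[i], edges[i+1])
  dvol <- f[-length(f)] - f[-1L]
  mid <- (edges[-length(edges)] + edges[-1L]) / 2
  bed_mid <- bed(mid, n, ab)
  total <- sum(dvol)
  bed_mean <- if (total > 0) sum(dvol * bed_mid) / total else 0
  bed_curve <- tibble(bed = bed(edges, n, ab), fraction = f)
  list(bed_curve = bed_curve, bed_mean = bed_mean)
}

#' Ratio of fractional volumes between two DVH curves
#'
#' Compares a test DVH to a reference DVH point-wise over the dose
#' sub-range `[D98_ref, D50_ref]` (the DVH shoulder region): at each
#' reference bin edge in the range the ratio `test fraction / reference
#' fraction` is formed. The summary statistic `max_abs_deviation` is
#' `max |ratio - 1|` over the range, used to quantify how well a
#' reduced-phase accumulation approximates the full 10-phase one.
#'
#' @param test,reference [compute_dvh()] curves.
#' @return A tibble of class `dvh_ratio` with columns `dose` and `ratio`,
#'   and attribute `max_abs_deviation`. Points with zero reference fraction
#'   are dropped with a warning.
#' @export
dvh_fractional_volume_ratio <- function(test, reference) {
  stopifnot(inherits(test, "dvh_curve"), inherits(reference, "dvh_curve"))
  d98 <- dose_at_volume(reference, 98)
  d50 <- dose_at_volume(reference, 50)
  sel <- reference$dose >= d98 - 1e-12 & reference$dose <= d50 + 1e-12
  if (!any(sel)) abort("reference DVH has no bins in [D98, D50]")
  d <- reference$dose[sel]
  ref_f <- reference$fraction[sel]
  test_f <- stats::approx(test$dose, test$fraction, xout = d, rule = 2)$y
  bad <- ref_f <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d points with zero reference fraction", sum(bad)))
    d <- d[!bad]; ref_f <- ref_f[!bad]; test_f <- test_f[!bad]
  }
  out <- tibble(dose = d, ratio = test_f / ref_f)
  attr(out, "range") <- c(d98 = d98, d50 = d50)
  attr(out, "max_abs_deviation") <- max(abs(out$ratio - 1))
  class(out) <- c("dvh_ratio", class(out))
  out
}

#' Centroid displacement between two respiratory phases
#'
#' Per-axis absolute displacement and its Euclidean magnitude
#' `r3D = sqrt(SI^2 + AP^2 + LR^2)` between two structure centroids (mm),
#' the standard summary of tumour motion range between the extreme phases.
#'
#' @param centroid_a,centroid_b Length-3 mm coordinates, order (LR, AP, SI)
#'   as returned by [mask_centroid()].
#' @return One-row tibble with columns `r3d_mm`, `si_mm`, `ap_mm`, `lr_mm`.
#' @examples
#' motion_vector(c(0, 0, 0), c(1.0, 0.5, 10.5))
#' @export
motion_vector <- function(centroid_a, centroid_b) {
  if (length(centroid_a) != 3L || length(centroid_b) != 3L ||
      any(!is.finite(centroid_a)) || any(!is.finite(centroid_b)))
    abort("centroids must be finite length-3 mm coordinates")
  d <- abs(centroid_b - centroid_a)
  tibble(r3d_mm = sqrt(sum(d^2)), si_mm = d[3], ap_mm = d[2], lr_mm = d[1])
}

#' Plan-quality metrics of a dose/structure pair
#'
#' One-row summary combining the DVH statistics reported for each structure
#' and calculation arm: mean dose, D2/D50/D95/D98, homogeneity index and
#' (when a fractionation scheme is given) the DVH-based mean BED.
#'
#' @inheritParams compute_dvh
#' @param scheme Optional [fractionation()] for the BED column.
#' @param tag Calculation arm label (e.g. `"3DREF"`, `"4D"`, `"4D_p3"`).
#' @return One-row tibble.
#' @export
dose_metrics <- function(dose, mask, scheme = NULL, bin_width = 0.01,
                         tag = NA_character_) {
  dvh <- compute_dvh(dose, mask, bin_width)
  dx <- dose_at_volume(dvh, c(2, 50, 95, 98))
  bed_mean <- if (!is.null(scheme)) bed_from_dvh(dvh, scheme)$bed_mean
              else NA_real_
  tibble(structure = mask$name, tag = tag,
         volume_cc = volume_cc(mask),
         dmean_gy = mean_dose(dose, mask),
         d2_gy = dx[1], d50_gy = dx[2], d95_gy = dx[3], d98_gy = dx[4],
         hi = homogeneity_index(dx[1], dx[4]),
         bed_mean_gy = bed_mean)
}
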