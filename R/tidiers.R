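#' Tidy a DVH curve into a plain tibble
#'
#' @param x A [compute_dvh()] curve.
#' @param ... Unused.
#' @return Tibble with `structure`, `dose` (Gy) and `fraction`.
#' @export
tidy.dvh_curve <- function(x, ...) {
  tibble(structure = attr(x, "structure"), dose = x$dose,
         fraction = x$fraction)
}

#' One-row summary of a DVH curve
#'
#' @param x A [compute_dvh()] curve.
#' @param ... Unused.
#' @return Tibble with structure name, volume, bin width and the standard
#'   Dx statistics.
#' @export
glance.dvh_curve <- function(x, ...) {
  dx <- dose_at_volume(x, c(2, 50, 95, 98))
  tibble(structure = attr(x, "structure"),
         total_volume_cc = attr(x, "total_volume_cc"),
         bin_width = attr(x, "bin_width"),
         d2_gy = dx[1], d50_gy = dx[2], d95_gy = dx[3], d98_gy = dx[4],
         hi = homogeneity_index(dx[1], dx[4]))
}

#' Per-level iteration table of a registration
#'
#' @param x A [register_volumes()] result.
#' @param ... Unused.
#' @return Tibble with one row per pyramid level.
#' @export
tidy.registration_result <- function(x, ...) x$levels

#' One-row summary of a registration
#'
#' @param x A [register_volumes()] result.
#' @param ... Unused.
#' @return Tibble with pre/post cross-correlation and field magnitude
#'   statistics.
#' @export
glance.registration_result <- function(x, ...) {
  mag <- sqrt(x$dvf$ux^2 + x$dvf$uy^2 + x$dvf$uz^2)
  tibble(cc_pre = x$cross_correlation_pre,
         cc_post = x$cross_correlation_post,
         mean_abs_mm = mean(mag), max_abs_mm = max(mag),
         iterations = sum(x$levels$iterations))
}

#' Long metric table of a study report
#'
#' @param x A [run_study()] report.
#' @param ... Unused.
#' @return Tibble with one row per structure x arm x metric.
#' @export
tidy.study_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics,
                      cols = c("dmean_gy", "d2_gy", "d50_gy", "d95_gy",
                               "d98_gy", "hi", "bed_mean_gy"),
                      names_to = "metric", values_to = "value")
}

#' Headline summary of a study report
#'
#' @param x A [run_study()] report.
#' @param ... Unused.
#' @return One-row tibble with the headline 3D-vs-4D comparison: PTV D98
#'   and HI under both arms, the normal-liver mean-dose difference, and the
#'   oracle agreement.
#' @export
glance.study_report <- function(x, ...) {
  pick <- function(st, arm, col)
    x$metrics[[col]][x$metrics$structure == st & x$metrics$tag == arm]
  tibble(
    ptv_d98_3d_gy = pick("PTV", "3DREF", "d98_gy"),
    ptv_d98_4d_gy = pick("PTV", "4D", "d98_gy"),
    ptv_hi_3d = pick("PTV", "3DREF", "hi"),
    ptv_hi_4d = pick("PTV", "4D", "hi"),
    ptv_hi_ratio_pct = hi_ratio_percent(pick("PTV", "3DREF", "hi"),
                                        pick("PTV", "4D", "hi")),
    normal_liver_dmean_3d_gy = pick("normal_liver", "3DREF", "dmean_gy"),
    normal_liver_dmean_4d_gy = pick("normal_liver", "4D", "dmean_gy"),
    oracle_liver_agreement_pct = x$oracle$liver_agreement_pct)
}
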