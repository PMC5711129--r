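#' Configuration of a full 3D-vs-4D evaluation study
#'
#' Bundles every parameter of the pipeline: phantom geometry, motion model,
#' dose prescription, registration settings, the phase subsets to evaluate,
#' and the seed. All defaults reproduce the package's reference study
#' conditions (96^3 phantom at 3 mm, lesion-E motion, 42 Gy in 6 fractions
#' prescribed to the 80% covering isodose).
#'
#' @param spec A [phantom_spec()].
#' @param motion A [motion_model()].
#' @param dose A [dose_model()].
#' @param registration A [registration_params()].
#' @param subsets Reduced phase subsets to accumulate in addition to the
#'   full `p10` (see [phase_subset()]).
#' @param margin_mm PTV margin (mm).
#' @param itv_mode `"union"` or `"intersection"` of the extreme-phase GTVs.
#' @param bin_width DVH bin width (Gy).
#' @param alpha_beta_tumor,alpha_beta_liver Tissue alpha/beta ratios (Gy)
#'   for target and normal-liver BED.
#' @param seed Integer seed controlling the phantom noise.
#' @param outdir Optional directory; when given, [run_study()] writes
#'   volumes, CSV tables and a JSON report there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(spec = phantom_spec(), motion = motion_model(),
                         dose = dose_model(),
                         registration = registration_params(),
                         subsets = c("p2", "p3", "p5even", "p5odd"),
                         margin_mm = 5,
                         itv_mode = c("union", "intersection"),
                         bin_width = 0.01,
                         alpha_beta_tumor = 10, alpha_beta_liver = 2,
                         seed = 1L, outdir = NULL) {
  itv_mode <- match.arg(itv_mode)
  stopifnot(inherits(spec, "phantom_spec"), inherits(motion, "motion_model"),
            inherits(dose, "dose_model"),
            inherits(registration, "registration_params"))
  bad <- setdiff(subsets, c("p2", "p3", "p5even", "p5odd", "p10"))
  if (length(bad) > 0)
    abort(sprintf("unknown phase subset(s): %s", paste(bad, collapse = ", ")))
  structure(list(spec = spec, motion = motion, dose = dose,
                 registration = registration, subsets = subsets,
                 margin_mm = margin_mm, itv_mode = itv_mode,
                 bin_width = bin_width,
                 alpha_beta_tumor = alpha_beta_tumor,
                 alpha_beta_liver = alpha_beta_liver,
                 seed = as.integer(seed), outdir = outdir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Every entry is optional and overrides the corresponding
#' [study_config()] default; nested blocks `phantom`, `motion`, `dose` and
#' `registration` override the arguments of the respective constructors.
#'
#' @param path Path to a YAML document.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing file: '%s'", path))
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  amp <- y$motion$amplitude
  margs <- y$motion %||% list()
  if (!is.null(amp)) margs$amplitude <- as.numeric(amp)
  top <- y[setdiff(names(y), c("phantom", "motion", "dose", "registration"))]
  do.call(study_config, c(
    list(spec = build(phantom_spec, y$phantom),
         motion = build(motion_model, margs),
         dose = build(dose_model, y$dose),
         registration = build(registration_params, y$registration)),
    top))
}

#' Run the full 3D-vs-4D dose evaluation study
#'
#' Executes the complete workflow on the configured phantom: generates the
#' 10 phase CTs and analytic masks, builds the AIP and the ITV/PTV targets,
#' places the static conformal dose, registers the 9 non-reference phases
#' to the end-expiration reference, warps the static dose through each
#' estimated field, accumulates equal-weighted 4D doses for the full 10
#' phases and every configured subset, computes plan-quality metrics for
#' every structure under each calculation arm, and assembles the 3D-vs-4D
#' comparison. The analytic ground-truth accumulated dose is carried along
#' as the registration-free oracle. Fully deterministic given the seed.
#'
#' Calculation arms: `3DREF` (static dose, reference-phase contours, normal
#' liver = liver minus GTV), `3DAIP` (static dose, AIP-style contours,
#' normal liver = liver minus ITV), `4D` (10-phase accumulated dose,
#' reference contours) and `4D_p*` for the reduced subsets.
#'
#' @param config A [study_config()].
#' @param dry_run If `TRUE`, validate the configuration and return the
#'   execution plan without computing.
#' @return An object of class `study_report`; see [tidy.study_report()],
#'   [glance.study_report()], [subset_convergence_study()].
#' @export
run_study <- function(config = study_config(), dry_run = FALSE) {
  stopifnot(inherits(config, "study_config"))
  spec <- config$spec
  motion <- config$motion
  phases <- phase_labels(motion$n_phases)
  ref <- motion$reference_phase
  if (dry_run) {
    return(list(phases = phases, reference = ref,
                subsets = config$subsets,
                grid = spec$grid, seed = config$seed))
  }

  cts <- lapply(phases, function(ph)
    generate_phase_ct(spec, motion, ph, seed = config$seed))
  names(cts) <- phases
  masks_ref <- generate_phase_masks(spec, motion, ref)
  gtv_inhale <- generate_phase_masks(spec, motion, "0%")$gtv
  aip <- average_intensity_projection(cts)
  targets <- build_targets(masks_ref$gtv, gtv_inhale,
                           margin_mm = config$margin_mm,
                           itv_mode = config$itv_mode)
  gtv5 <- expand_margin(masks_ref$gtv, config$margin_mm, name = "GTV+5mm")
  static_dose <- generate_static_dose(spec, config$dose, targets$ptv)

  # deformable registration of each non-reference phase to the reference
  registrations <- list()
  dvfs <- list()
  zero <- array(0, spec$grid$shape)
  for (ph in phases) {
    if (ph == ref) {
      dvfs[[ph]] <- vector_field(zero, zero, zero, spec$grid)
      next
    }
    reg <- register_volumes(cts[[ph]], cts[[ref]], config$registration)
    registrations[[ph]] <- reg
    dvfs[[ph]] <- reg$dvf
  }
  warped <- lapply(phases, function(ph) warp_dose(static_dose, dvfs[[ph]]))
  names(warped) <- phases

  subset_names <- union("p10", config$subsets)
  accumulated <- lapply(subset_names, function(s) {
    ps <- phase_subset(s)
    accumulate_dose(warped[ps$members], ps$weights)
  })
  names(accumulated) <- subset_names
  oracle_acc <- ground_truth_accumulated_dose(motion, static_dose,
                                              spec = spec)

  # structures with their BED fractionation
  sch_t <- fractionation(config$dose$n_fractions, config$alpha_beta_tumor)
  sch_l <- fractionation(config$dose$n_fractions, config$alpha_beta_liver)
  normal_liver_ref <- mask_boolean(masks_ref$liver, masks_ref$gtv,
                                   "difference", name = "normal_liver")
  normal_liver_aip <- mask_boolean(masks_ref$liver, targets$itv,
                                   "difference", name = "normal_liver")
  target_structs <- list(GTV = masks_ref$gtv, ITV = targets$itv,
                         PTV = targets$ptv, `GTV+5mm` = gtv5)

  arm_doses <- c(list(`3DREF` = static_dose, `3DAIP` = static_dose,
                      `4D` = accumulated$p10),
                 stats::setNames(
                   accumulated[setdiff(subset_names, "p10")],
                   paste0("4D_", setdiff(subset_names, "p10"))))
  metric_rows <- list()
  for (arm in names(arm_doses)) {
    dose_arm <- arm_doses[[arm]]
    for (sn in names(target_structs)) {
      metric_rows[[length(metric_rows) + 1L]] <-
        dose_metrics(dose_arm, target_structs[[sn]], scheme = sch_t,
                     bin_width = config$bin_width, tag = arm)
    }
    nl <- if (arm == "3DAIP") normal_liver_aip else normal_liver_ref
    metric_rows[[length(metric_rows) + 1L]] <-
      dose_metrics(dose_arm, nl, scheme = sch_l,
                   bin_width = config$bin_width, tag = arm)
  }
  metrics <- dplyr::bind_rows(metric_rows)

  diffs <- compute_arm_differences(metrics)

  phase_diff <- tibble(
    phase = phases,
    max_point_diff_liver_pct = vapply(phases, function(ph)
      max_point_difference_pct(dose_difference_map(warped[[ph]], static_dose),
                               masks_ref$liver, config$dose$prescription),
      numeric(1), USE.NAMES = FALSE))

  reg_summary <- dplyr::bind_rows(lapply(names(registrations), function(ph) {
    r <- registrations[[ph]]
    tibble(phase = ph,
           cc_pre = r$cross_correlation_pre,
           cc_post = r$cross_correlation_post,
           iterations = sum(r$levels$iterations))
  }))

  err <- abs(accumulated$p10$values - oracle_acc$values)
  tol_gy <- 0.02 * config$dose$prescription
  oracle <- tibble(
    liver_agreement_pct =
      100 * mean(err[masks_ref$liver$member] <= tol_gy),
    tolerance_gy = tol_gy,
    max_liver_error_gy = max(err[masks_ref$liver$member]))

  dvhs <- lapply(subset_names, function(s)
    list(PTV = compute_dvh(accumulated[[s]], targets$ptv, config$bin_width),
         normal_liver = compute_dvh(accumulated[[s]], normal_liver_ref,
                                    config$bin_width)))
  names(dvhs) <- subset_names

  report <- structure(list(
    metrics = metrics, diffs = diffs, phase_diff = phase_diff,
    registration = reg_summary, oracle = oracle,
    subset_dvhs = dvhs,
    doses = c(list(static = static_dose, oracle = oracle_acc), accumulated),
    warped = warped,
    masks = c(target_structs,
              list(liver = masks_ref$liver, body = masks_ref$body,
                   normal_liver = normal_liver_ref,
                   normal_liver_aip = normal_liver_aip)),
    aip = aip, cts = cts, dvfs = dvfs,
    provenance = list(seed = config$seed,
                      package_version = as.character(
                        utils::packageVersion("dosewarp")),
                      grid_shape = spec$grid$shape,
                      grid_spacing = spec$grid$spacing,
                      amplitude_mm = motion$amplitude,
                      waveform = motion$waveform,
                      prescription_gy = config$dose$prescription,
                      n_fractions = config$dose$n_fractions,
                      covering_isodose = config$dose$covering_isodose,
                      penumbra_sigma_mm = config$dose$penumbra_sigma,
                      itv_mode = config$itv_mode,
                      subsets = subset_names,
                      registration = unclass(config$registration)),
    config = config), class = "study_report")
  if (!is.null(config$outdir)) write_study_report(report, config$outdir)
  report
}

# Pairwise (3D - 4D)/4D percent differences and HI ratio per structure.
compute_arm_differences <- function(metrics) {
  m3 <- metrics[metrics$tag == "3DREF", ]
  m4 <- metrics[metrics$tag == "4D", ]
  joined <- dplyr::inner_join(m3, m4, by = "structure",
                              suffix = c("_3d", "_4d"))
  dplyr::transmute(joined,
    structure = .data$structure,
    dmean_pct_diff = 100 * (.data$dmean_gy_3d - .data$dmean_gy_4d) /
      .data$dmean_gy_4d,
    d2_pct_diff = 100 * (.data$d2_gy_3d - .data$d2_gy_4d) / .data$d2_gy_4d,
    d98_pct_diff = 100 * (.data$d98_gy_3d - .data$d98_gy_4d) /
      .data$d98_gy_4d,
    bed_mean_pct_diff = 100 * (.data$bed_mean_gy_3d - .data$bed_mean_gy_4d) /
      .data$bed_mean_gy_4d,
    hi_3d = .data$hi_3d,
    hi_4d = .data$hi_4d,
    hi_ratio_pct = hi_ratio_percent(.data$hi_3d, .data$hi_4d))
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  grid %s, seed %d\n",
              paste(x$provenance$grid_shape, collapse = "x"),
              x$provenance$seed))
  cat(sprintf("  oracle: %.1f%% of liver voxels within %.2f Gy of the analytic 4D dose\n",
              x$oracle$liver_agreement_pct, x$oracle$tolerance_gy))
  cat("  3D vs 4D differences:\n")
  print(x$diffs)
  invisible(x)
}

#' Convergence of reduced-phase accumulations towards the 10-phase dose
#'
#' For each configured subset, compares the subset DVH to the full
#' 10-phase DVH over the reference `[D98, D50]` dose range (see
#' [dvh_fractional_volume_ratio()]) for the PTV and the normal liver.
#' Deviations are expected to shrink as more phases are used; a violation
#' of that ordering is reported with a warning, not an error.
#'
#' @param report A [run_study()] result.
#' @return A tibble with one row per subset x structure and the
#'   `max_abs_deviation_pct` summary.
#' @export
subset_convergence_study <- function(report) {
  stopifnot(inherits(report, "study_report"))
  subsets <- setdiff(names(report$subset_dvhs), "p10")
  if (length(subsets) == 0) abort("no reduced subsets in this report")
  rows <- list()
  for (s in subsets) {
    for (st in c("PTV", "normal_liver")) {
      r <- dvh_fractional_volume_ratio(report$subset_dvhs[[s]][[st]],
                                       report$subset_dvhs$p10[[st]])
      rows[[length(rows) + 1L]] <- tibble(
        subset = s, structure = st, n_phases = length(phase_subset(s)$members),
        max_abs_deviation_pct = 100 * attr(r, "max_abs_deviation"))
    }
  }
  out <- dplyr::bind_rows(rows)
  ord <- out |>
    dplyr::group_by(.data$n_phases) |>
    dplyr::summarise(dev = max(.data$max_abs_deviation_pct)) |>
    dplyr::arrange(.data$n_phases)
  if (is.unsorted(rev(ord$dev), strictly = FALSE))
    warn("subset deviations are not monotone in the number of phases")
  out
}

#' Write the study outputs to a directory
#'
#' Emits the static, oracle and accumulated dose volumes plus the AIP as
#' NRRD, the structure masks as uint8 NRRD, the estimated fields, and the
#' metric/difference/registration tables as CSV with a JSON report mirroring
#' them. Output is deterministic: rerunning the same seeded study produces
#' byte-identical CSV and JSON.
#'
#' @param report A [run_study()] result.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_study_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wr <- function(p) {
    paths <<- c(paths, p)
    p
  }
  for (nm in names(report$doses))
    write_volume(report$doses[[nm]],
                 wr(file.path(outdir, sprintf("dose_%s.nrrd", nm))))
  write_volume(report$aip, wr(file.path(outdir, "ct_aip.nrrd")))
  for (nm in names(report$masks))
    write_mask(report$masks[[nm]],
               wr(file.path(outdir, sprintf("mask_%s.nrrd",
                                            gsub("[+]", "plus", nm)))))
  for (ph in names(report$dvfs))
    write_vector_field(report$dvfs[[ph]],
                       wr(file.path(outdir, sprintf("dvf_phase_%s.nrrd",
                                                    sub("%", "", ph)))))
  utils::write.csv(report$metrics, wr(file.path(outdir, "metrics.csv")),
                   row.names = FALSE)
  utils::write.csv(report$diffs, wr(file.path(outdir, "differences.csv")),
                   row.names = FALSE)
  utils::write.csv(report$registration,
                   wr(file.path(outdir, "registration.csv")),
                   row.names = FALSE)
  utils::write.csv(report$phase_diff,
                   wr(file.path(outdir, "phase_max_point_diff.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(provenance = report$provenance,
         oracle = as.list(report$oracle),
         metrics = report$metrics, differences = report$diffs),
    wr(file.path(outdir, "report.json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
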