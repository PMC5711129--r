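#' Phase labels of an n-phase respiratory cycle
#'
#' Phases are labelled by percentage of the breathing period, `"0%"` through
#' `"90%"` for the standard 10-phase binning; `"0%"` is end-inspiration and
#' `"50%"` end-expiration.
#'
#' @param n_phases Number of equally spaced phase bins.
#' @return Character vector of labels.
#' @export
phase_labels <- function(n_phases = 10L) {
  paste0(round(seq(0L, n_phases - 1L) * 100 / n_phases), "%")
}

phase_index <- function(phase, n_phases = 10L) {
  labels <- phase_labels(n_phases)
  idx <- match(phase, labels)
  if (any(is.na(idx)))
    abort(sprintf("unknown phase label '%s' (expected one of %s)",
                  paste(phase[is.na(idx)], collapse = ", "),
                  paste(labels, collapse = ", ")))
  idx - 1L
}

#' Analytic respiratory motion model
#'
#' Displacement of tissue at reference-frame position `x` in phase `k` is
#' `d_k(x) = w_k * envelope(x) * amplitude` per axis: a separable product of
#' a phase waveform `w_k` in `[0, 1]` (0 at the end-expiration reference
#' phase, 1 at end-inspiration `0%`), a smooth spatial envelope in `[0, 1]`
#' (1 throughout the liver region, decaying to 0 at the body surface so the
#' couch-side boundary is fixed), and per-axis amplitudes in mm.
#'
#' Default amplitudes (LR 1.1, AP 1.6, SI 10.5 mm) correspond to the bundled
#' lesion preset `"E"`; see [lesion_presets()] for all five presets spanning
#' 7.5-16.5 mm superior-inferior motion.
#'
#' @param amplitude Length-3 numeric, mm, order (LR, AP, SI).
#' @param n_phases Number of phase bins (default 10).
#' @param reference_phase Label of the zero-displacement phase
#'   (default `"50%"`, end-expiration).
#' @param waveform `"cosine"` (`w_k = (1 + cos(2*pi*k/n))/2`) or `"cos4"`
#'   (its square, mimicking a longer end-expiration dwell).
#' @param envelope Optional function mapping an `n x 3` matrix of mm
#'   coordinates to envelope weights in `[0, 1]`. When `NULL` the generator
#'   functions derive it from their [phantom_spec()].
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(amplitude = c(lr = 1.1, ap = 1.6, si = 10.5),
                         n_phases = 10L, reference_phase = "50%",
                         waveform = c("cosine", "cos4"), envelope = NULL) {
  waveform <- match.arg(waveform)
  amplitude <- as.numeric(amplitude)
  if (length(amplitude) != 3L || any(!is.finite(amplitude)))
    abort("`amplitude` must be three finite numbers (mm), order (LR, AP, SI)")
  n_phases <- as.integer(n_phases)
  k <- seq_len(n_phases) - 1L
  w <- (1 + cos(2 * pi * k / n_phases)) / 2
  if (waveform == "cos4") w <- w^2
  names(w) <- phase_labels(n_phases)
  kref <- phase_index(reference_phase, n_phases)
  if (abs(w[kref + 1L]) > 1e-12)
    abort("waveform is not zero at the reference phase")
  if (abs(max(w) - 1) > 1e-12)
    abort("waveform maximum must be 1")
  structure(list(amplitude = amplitude, n_phases = n_phases,
                 reference_phase = reference_phase, waveform = waveform,
                 w = w, envelope = envelope),
            class = "motion_model")
}

#' Geometry and tissue parameters of the digital liver phantom
#'
#' The phantom is an ellipsoidal soft-tissue body in air containing an
#' ellipsoidal liver with an embedded spherical tumour seated towards the
#' liver dome, so that the superior dose penumbra falls outside the liver
#' while the inferior penumbra lies within it — the asymmetry that drives
#' the normal-liver dose effects of 4D evaluation. A smooth
#' low-amplitude sinusoidal texture is added inside the body (advected with
#' the tissue) so that deformable registration has intensity structure to
#' work with away from organ boundaries, and seeded Gaussian noise emulates
#' CT image noise. Default geometry: 96^3 voxels at 3 mm spacing with the
#' tumour volume matching lesion preset `"E"` (86.2 cm^3).
#'
#' @param shape,spacing Grid size and spacing (mm).
#' @param origin Grid origin; default centres the grid on (0, 0, 0).
#' @param body_center,body_radii Body ellipsoid centre / semi-axes (mm).
#' @param liver_center,liver_radii Liver ellipsoid centre / semi-axes (mm).
#' @param tumor_center,tumor_radius Tumour sphere centre / radius (mm).
#' @param hu Named HU values for `air`, `soft`, `liver`, `tumor`.
#' @param texture_amp Amplitude (HU) of the smooth intra-body texture.
#' @param texture_wavelength Length-3 texture wavelengths (mm).
#' @param noise_sd Additive Gaussian noise SD in HU (seeded).
#' @param psf_sigma Gaussian point-spread width (mm) emulating the
#'   scanner/reconstruction partial-volume blur applied to the imaged
#'   anatomy (0 disables it; masks and dose are unaffected).
#' @param envelope_core Ellipsoidal body coordinate inside which the motion
#'   envelope is exactly 1 (the liver must sit within it).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96L, 96L, 96L), spacing = c(3, 3, 3),
                         origin = NULL,
                         body_center = c(0, 0, 0),
                         body_radii = c(130, 110, 135),
                         liver_center = c(20, 0, 10),
                         liver_radii = c(75, 55, 65),
                         tumor_center = c(20, 0, 35),
                         tumor_radius = 27.4,
                         hu = c(air = -1000, soft = 40, liver = 60,
                                tumor = 100),
                         texture_amp = 40, texture_wavelength = c(25, 22.5, 29),
                         noise_sd = 10, psf_sigma = 2, envelope_core = 0.8) {
  origin <- origin %||% (-spacing * (shape - 1) / 2)
  grid <- grid3d(shape, spacing, origin)
  if (any(hu < -1024) || any(hu > 3071))
    abort("tissue HU values must lie within [-1024, 3071]")
  spec <- structure(list(grid = grid, body_center = body_center,
                         body_radii = body_radii,
                         liver_center = liver_center,
                         liver_radii = liver_radii,
                         tumor_center = tumor_center,
                         tumor_radius = tumor_radius, hu = hu,
                         texture_amp = texture_amp,
                         texture_wavelength = texture_wavelength,
                         noise_sd = noise_sd, psf_sigma = psf_sigma,
                         envelope_core = envelope_core),
                    class = "phantom_spec")
  # tumor within liver within body (at rest)
  if (ellipsoid_rho(matrix(tumor_center, 1), liver_center,
                    liver_radii - tumor_radius) > 1)
    abort("tumor sphere must lie inside the liver ellipsoid")
  spec
}

# normalised ellipsoidal radial coordinate (1 on the surface)
ellipsoid_rho <- function(pts, center, radii) {
  sqrt(((pts[, 1] - center[1]) / radii[1])^2 +
       ((pts[, 2] - center[2]) / radii[2])^2 +
       ((pts[, 3] - center[3]) / radii[3])^2)
}

# smoothstep envelope: 1 for body coordinate <= core, 0 at the body surface
envelope_fn <- function(spec) {
  core <- spec$envelope_core
  function(pts) {
    rho <- ellipsoid_rho(pts, spec$body_center, spec$body_radii)
    s <- pmin(pmax((rho - core) / (1 - core), 0), 1)
    1 - s^2 * (3 - 2 * s)
  }
}

resolve_envelope <- function(model, spec = NULL) {
  model$envelope %||%
    (if (!is.null(spec)) envelope_fn(spec)
     else envelope_fn(phantom_spec()))
}

#' Forward ground-truth displacement of the motion model
#'
#' Maps reference-frame (end-expiration) positions to their displaced
#' positions in the requested phase: `x_phase = x + d(x, phase)`. This is the
#' analytic field against which registration-estimated fields and warped
#' doses are benchmarked, and it is also exactly the pull-back field that
#' [warp_dose()] needs to map a phase dose onto the reference anatomy under
#' the static dose-cloud model.
#'
#' @param model A [motion_model()].
#' @param phase Phase label, e.g. `"0%"`.
#' @param points `n x 3` matrix of reference positions (mm).
#' @param spec Optional [phantom_spec()] supplying the spatial envelope when
#'   the model carries none.
#' @return `n x 3` matrix of displacements (mm).
#' @export
forward_displacement <- function(model, phase, points, spec = NULL) {
  stopifnot(inherits(model, "motion_model"))
  points <- as.matrix(points)
  w <- model$w[phase_index(phase, model$n_phases) + 1L]
  env <- resolve_envelope(model, spec)(points)
  cbind(w * env * model$amplitude[1],
        w * env * model$amplitude[2],
        w * env * model$amplitude[3])
}

# Pull-back displacement v with x_ref = y + v(y): fixed-point iteration on
# v = -d(y + v). Converges fast because the field is smooth and moderate.
inverse_displacement <- function(model, phase, points, spec = NULL,
                                 iterations = 8L) {
  points <- as.matrix(points)
  w <- model$w[phase_index(phase, model$n_phases) + 1L]
  if (w == 0) return(matrix(0, nrow(points), 3L))
  env <- resolve_envelope(model, spec)
  amp <- model$amplitude
  v <- matrix(0, nrow(points), 3L)
  for (i in seq_len(iterations)) {
    e <- env(points + v)
    v <- cbind(-w * e * amp[1], -w * e * amp[2], -w * e * amp[3])
  }
  v
}

# Reference-frame tissue model: HU as an analytic function of position.
tissue_hu <- function(spec, pts) {
  hu <- rep(spec$hu[["air"]], nrow(pts))
  in_body <- ellipsoid_rho(pts, spec$body_center, spec$body_radii) <= 1
  hu[in_body] <- spec$hu[["soft"]]
  in_liver <- ellipsoid_rho(pts, spec$liver_center, spec$liver_radii) <= 1
  hu[in_liver] <- spec$hu[["liver"]]
  r <- sqrt((pts[, 1] - spec$tumor_center[1])^2 +
            (pts[, 2] - spec$tumor_center[2])^2 +
            (pts[, 3] - spec$tumor_center[3])^2)
  hu[r <= spec$tumor_radius] <- spec$hu[["tumor"]]
  if (spec$texture_amp > 0) {
    # sum of oblique plane waves: smooth quasi-random structure whose
    # gradient vanishes only at isolated points, so registration has
    # anchoring intensity information throughout the body
    lam <- spec$texture_wavelength
    dirs <- rbind(c(0.8, 0.36, 0.48), c(-0.48, 0.8, 0.36),
                  c(0.36, -0.48, 0.8))
    ph <- c(0.7, 1.9, 3.1)
    tex <- 0
    for (i in 1:3) {
      k <- 2 * pi * dirs[i, ] / lam[i]
      tex <- tex + sin(pts %*% k + ph[i])
    }
    tex <- spec$texture_amp / sqrt(3) * as.numeric(tex)
    hu[in_body] <- hu[in_body] + tex[in_body]
  }
  hu
}

#' Generate one CT phase of the 4D phantom
#'
#' Voxel HU is the reference tissue model evaluated at the pulled-back
#' position (the analytic inverse of the forward motion map), plus seeded
#' Gaussian noise; output is a pure function of `(spec, model, phase, seed)`.
#'
#' @param spec A [phantom_spec()].
#' @param model A [motion_model()].
#' @param phase Phase label.
#' @param seed Integer seed for the additive noise.
#' @return A [scalar_volume()] in HU.
#' @export
generate_phase_ct <- function(spec, model, phase, seed = 1L) {
  pts <- voxel_centers(spec$grid)
  v <- inverse_displacement(model, phase, pts, spec)
  hu <- tissue_hu(spec, pts + v)
  if (spec$psf_sigma > 0) {
    hu <- as.numeric(gauss_smooth(array(hu, spec$grid$shape),
                                  spec$psf_sigma / spec$grid$spacing,
                                  renormalize = TRUE))
  }
  if (spec$noise_sd > 0) {
    k <- phase_index(phase, model$n_phases)
    noise <- with_seed_local(as.integer(seed) + 101L * k,
                             rnorm(nrow(pts), sd = spec$noise_sd))
    hu <- hu + noise
  }
  scalar_volume(array(hu, dim = spec$grid$shape), spec$grid, unit = "HU")
}

#' Generate the analytic structure masks for one phase
#'
#' Masks are the analytic reference shapes evaluated under the phase
#' deformation (no noise): a voxel is a member iff its pulled-back centre
#' lies inside the shape. The GTV is contained in the liver on every phase
#' by construction.
#'
#' @inheritParams generate_phase_ct
#' @return Named list of [structure_mask()]: `gtv`, `liver`, `body`.
#' @export
generate_phase_masks <- function(spec, model, phase) {
  pts <- voxel_centers(spec$grid)
  v <- inverse_displacement(model, phase, pts, spec)
  p0 <- pts + v
  shp <- spec$grid$shape
  r <- sqrt((p0[, 1] - spec$tumor_center[1])^2 +
            (p0[, 2] - spec$tumor_center[2])^2 +
            (p0[, 3] - spec$tumor_center[3])^2)
  list(
    gtv = structure_mask(array(r <= spec$tumor_radius, shp), spec$grid, "GTV"),
    liver = structure_mask(
      array(ellipsoid_rho(p0, spec$liver_center, spec$liver_radii) <= 1, shp),
      spec$grid, "liver"),
    body = structure_mask(
      array(ellipsoid_rho(p0, spec$body_center, spec$body_radii) <= 1, shp),
      spec$grid, "body"))
}

#' Conformal dose prescription model
#'
#' @param prescription Prescribed dose (Gy) at the covering isodose.
#' @param n_fractions Number of fractions it is delivered in.
#' @param covering_isodose Fraction of the maximum dose at which the
#'   prescription covers the target (default 0.80, so the maximum dose is
#'   `prescription / 0.8 = 125%` of prescription).
#' @param penumbra_sigma Gaussian penumbra width outside the target (mm).
#' @param halo_fraction Peak of the broad low-dose component (entrance/exit
#'   beam dose bathing the surrounding organ) as a fraction of the maximum
#'   dose; 0 disables it, leaving the pure conformal component.
#' @param halo_sigma Width (mm) of the low-dose halo.
#' @return An object of class `dose_model`.
#' @export
dose_model <- function(prescription = 42, n_fractions = 6L,
                       covering_isodose = 0.80, penumbra_sigma = 5,
                       halo_fraction = 0.12, halo_sigma = 45) {
  if (!is_number(prescription) || prescription <= 0)
    abort("`prescription` must be a positive dose in Gy")
  if (!is_number(covering_isodose) || covering_isodose <= 0 ||
      covering_isodose > 1)
    abort("`covering_isodose` must be in (0, 1]")
  if (!is_number(penumbra_sigma) || penumbra_sigma <= 0)
    abort("`penumbra_sigma` must be positive (mm)")
  if (!is_number(halo_fraction) || halo_fraction < 0 || halo_fraction >= 1)
    abort("`halo_fraction` must lie in [0, 1)")
  if (!is_number(halo_sigma) || halo_sigma <= 0)
    abort("`halo_sigma` must be positive (mm)")
  structure(list(prescription = prescription,
                 n_fractions = as.integer(n_fractions),
                 covering_isodose = covering_isodose,
                 penumbra_sigma = penumbra_sigma,
                 halo_fraction = halo_fraction,
                 halo_sigma = halo_sigma),
            class = "dose_model")
}

#' Generate the static conformal dose distribution
#'
#' The dose is `Dmax * G(x)` with `Dmax = prescription / covering_isodose`.
#' `G` is built from a Gaussian blur (width `penumbra_sigma`) of the PTV
#' mask, rescaled and clamped so that the covering isodose surface passes
#' through the 95%-volume depth of the PTV: the flat core at `Dmax` fills
#' the PTV interior, `D95(PTV)` equals the prescription by construction,
#' and outside the PTV the dose falls off as a Gaussian tail of width
#' `penumbra_sigma`. When `halo_fraction > 0` a broad low-dose component
#' (width `halo_sigma`, peak `halo_fraction * Dmax`) is overlaid via a
#' voxel-wise maximum, emulating the entrance/exit beam dose that bathes
#' the organ hosting the target; with `halo_fraction = 0` the far field
#' decays to zero as the pure Gaussian tail.
#'
#' @param spec A [phantom_spec()] (supplies the grid).
#' @param model A [dose_model()].
#' @param ptv A non-empty [structure_mask()] on the phantom grid.
#' @return A [scalar_volume()] in Gy.
#' @export
generate_static_dose <- function(spec, model, ptv) {
  stopifnot(inherits(model, "dose_model"), inherits(ptv, "structure_mask"))
  if (!any(ptv$member)) abort("empty PTV: cannot place a dose distribution")
  if (!grid_equal(spec$grid, ptv$grid))
    abort("grid mismatch: PTV must be on the phantom grid")
  sigma_vox <- model$penumbra_sigma / spec$grid$spacing
  blur <- gauss_smooth(array(as.numeric(ptv$member), dim = spec$grid$shape),
                       sigma_vox, renormalize = FALSE)
  # calibrate: the blur value exceeded by 95% of PTV voxels maps to the
  # covering isodose, values above clamp to the maximum dose
  b05 <- quantile(blur[ptv$member], 0.05, type = 1, names = FALSE)
  g <- pmin(blur * (model$covering_isodose / b05), 1)
  if (model$halo_fraction > 0) {
    halo <- gauss_smooth(array(as.numeric(ptv$member),
                               dim = spec$grid$shape),
                         model$halo_sigma / spec$grid$spacing,
                         renormalize = FALSE)
    g <- pmax(g, model$halo_fraction * halo / max(halo))
  }
  dmax <- model$prescription / model$covering_isodose
  scalar_volume(array(dmax * g, dim = spec$grid$shape), spec$grid, unit = "Gy")
}

#' Analytic ground-truth accumulated dose
#'
#' The noise-free oracle for path-integrated dose accumulation: at each
#' reference voxel `x` it evaluates `sum_k weight_k * D(x + d_k(x))` using
#' the analytic forward displacements of the motion model (no registration
#' involved). Every pipeline estimate is benchmarked against this.
#'
#' @param model A [motion_model()].
#' @param static_dose A [scalar_volume()] in Gy (static dose cloud).
#' @param phases Phase labels to accumulate (default: all phases).
#' @param weights Per-phase weights summing to 1 (default: equal).
#' @param spec Optional [phantom_spec()] supplying the motion envelope.
#' @return A [scalar_volume()] in Gy on the reference grid.
#' @export
ground_truth_accumulated_dose <- function(model, static_dose, phases = NULL,
                                          weights = NULL, spec = NULL) {
  stopifnot(inherits(model, "motion_model"),
            inherits(static_dose, "scalar_volume"))
  phases <- phases %||% phase_labels(model$n_phases)
  weights <- weights %||% rep(1 / length(phases), length(phases))
  if (length(weights) != length(phases))
    abort("`weights` must have one entry per phase")
  if (abs(sum(weights) - 1) > 1e-9)
    abort("`weights` must sum to 1 (tolerance 1e-9)")
  pts <- voxel_centers(static_dose$grid)
  acc <- numeric(nrow(pts))
  for (i in seq_along(phases)) {
    d <- forward_displacement(model, phases[i], pts, spec)
    acc <- acc + weights[i] *
      sample_trilinear(static_dose, pts + d, policy = "constant", fill = 0)
  }
  scalar_volume(array(acc, dim = static_dose$grid$shape), static_dose$grid,
                unit = "Gy")
}

#' True displacement field of a phase, sampled on the phantom grid
#'
#' The analytic forward displacement evaluated at every voxel centre,
#' packaged as a [vector_field()] ready for [warp_dose()]. Useful as the
#' registration-free oracle DVF.
#'
#' @inheritParams generate_phase_masks
#' @return A [vector_field()].
#' @export
true_displacement_field <- function(spec, model, phase) {
  pts <- voxel_centers(spec$grid)
  d <- forward_displacement(model, phase, pts, spec)
  shp <- spec$grid$shape
  vector_field(array(d[, 1], shp), array(d[, 2], shp), array(d[, 3], shp),
               spec$grid)
}

#' Bundled lesion presets
#'
#' Five liver-SBRT lesion presets (A-E) spanning tumour volumes
#' 6.7-86.2 cm^3 and superior-inferior motion 7.5-16.5 mm, each with its
#' centroid motion range per axis, prescribed `D95` and fractionation.
#' `lesion_motion()` returns the corresponding [motion_model()].
#'
#' @return A tibble with one row per lesion.
#' @export
lesion_presets <- function() {
  tibble::tribble(
    ~lesion, ~gtv_cc, ~si_mm, ~ap_mm, ~lr_mm, ~d95_gy, ~dose_per_fraction_gy,
    ~n_fractions,
    "A", 22.7,  7.5, 4.6, 0.9, 43.7,  7.28, 6L,
    "B", 12.4, 10.5, 0.5, 1.0, 41.7,  6.95, 6L,
    "C", 54.5,  7.5, 0.0, 0.1, 46.3,  7.72, 6L,
    "D",  6.7, 16.5, 1.8, 1.2, 54.5, 10.90, 5L,
    "E", 86.2, 10.5, 1.6, 1.1, 44.5,  7.42, 6L)
}

#' @rdname lesion_presets
#' @param lesion One of `"A"` ... `"E"`.
#' @param ... Passed on to [motion_model()].
#' @export
lesion_motion <- function(lesion, ...) {
  tab <- lesion_presets()
  row <- tab[tab$lesion == lesion, ]
  if (nrow(row) != 1L)
    abort(sprintf("unknown lesion preset '%s'", lesion))
  motion_model(amplitude = c(lr = row$lr_mm, ap = row$ap_mm, si = row$si_mm),
               ...)
}
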