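#' Parameters for multi-resolution optical-flow registration
#'
#' The registration is a coarse-to-fine Horn-Schunck optical flow: at each
#' pyramid level the source image is warped by the current field, the
#' linearised brightness-constancy term is rebuilt, and Jacobi sweeps of the
#' Horn-Schunck update refine the field under a global smoothness prior.
#' Both images are linearly rescaled to `[0, 1]` over a shared HU window
#' before flow computation, so the smoothness weight is expressed in
#' normalised-intensity-per-voxel units.
#'
#' @param pyramid_levels Number of resolution levels (>= 1); level `l`
#'   subsamples by `2^(pyramid_levels - l)`.
#' @param iterations_per_level Total Jacobi sweeps allowed per level.
#' @param smoothness_weight Horn-Schunck regularisation weight `alpha`
#'   (the update uses `alpha^2`).
#' @param update_smoothing_sigma Optional Gaussian smoothing (mm) applied to
#'   the field after each relinearisation; 0 disables it.
#' @param convergence_tol Mean field update (mm) below which a level stops.
#' @param inner_iterations Relaxation sweeps between relinearisations
#'   (warps).
#' @param sor_omega Over-relaxation factor of the red-black Gauss-Seidel
#'   solver, in `(0, 2)`.
#' @param hu_window Length-2 HU window used for intensity normalisation.
#' @param presmooth_sigma Gaussian presmoothing (voxels) applied at the
#'   finest level to temper image noise.
#' @return An object of class `registration_params`.
#' @export
registration_params <- function(pyramid_levels = 3L,
                                iterations_per_level = 400L,
                                smoothness_weight = 0.05,
                                update_smoothing_sigma = 0,
                                convergence_tol = 1e-4,
                                inner_iterations = 20L,
                                sor_omega = 1.6,
                                hu_window = c(-200, 300),
                                presmooth_sigma = 0.7) {
  if (pyramid_levels < 1L) abort("`pyramid_levels` must be >= 1")
  if (iterations_per_level < 1L) abort("`iterations_per_level` must be >= 1")
  if (!is_number(smoothness_weight) || smoothness_weight <= 0)
    abort("`smoothness_weight` must be positive")
  if (convergence_tol <= 0) abort("`convergence_tol` must be positive (mm)")
  if (!is_number(sor_omega) || sor_omega <= 0 || sor_omega >= 2)
    abort("`sor_omega` must lie in (0, 2)")
  structure(list(pyramid_levels = as.integer(pyramid_levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 smoothness_weight = smoothness_weight,
                 update_smoothing_sigma = update_smoothing_sigma,
                 convergence_tol = convergence_tol,
                 inner_iterations = as.integer(inner_iterations),
                 sor_omega = sor_omega,
                 hu_window = hu_window,
                 presmooth_sigma = presmooth_sigma),
            class = "registration_params")
}

normalize_window <- function(values, window) {
  lo <- window[1]; hi <- window[2]
  pmin(pmax((values - lo) / (hi - lo), 0), 1)
}

# Smooth + subsample a full-resolution array by integer factor f.
pyramid_level <- function(a, grid, f) {
  if (f > 1L) a <- gauss_smooth(a, rep(f / 2, 3L), renormalize = TRUE)
  ix <- seq(1L, dim(a)[1], by = f)
  iy <- seq(1L, dim(a)[2], by = f)
  iz <- seq(1L, dim(a)[3], by = f)
  list(values = a[ix, iy, iz, drop = FALSE],
       grid = grid3d(c(length(ix), length(iy), length(iz)),
                     grid$spacing * f, grid$origin))
}

#' Deformable registration of two volumes (Horn-Schunck optical flow)
#'
#' Estimates a smooth displacement field `u` (mm, pull-back convention)
#' such that `source(x + u(x))` approximates `target(x)`. The field is
#' initialised to zero and the algorithm is fully deterministic, so
#' identical inputs give bit-identical fields. Registration quality is
#' summarised by the Pearson cross-correlation between target and (warped)
#' source; a warning (not an error) is raised if warping did not improve it.
#'
#' @param source,target [scalar_volume()] objects on the same grid
#'   (source = moving image, target = fixed/reference image).
#' @param params A [registration_params()].
#' @return An object of class `registration_result` with elements `dvf`
#'   ([vector_field()]), `warped_source`, `cross_correlation_pre`,
#'   `cross_correlation_post` and a per-level iteration table.
#' @export
register_volumes <- function(source, target, params = registration_params()) {
  stopifnot(inherits(source, "scalar_volume"),
            inherits(target, "scalar_volume"))
  check_same_grid(source, target, "source and target")
  if (any(!is.finite(source$values)) || any(!is.finite(target$values)))
    abort("non-finite voxels in input volumes")
  grid <- source$grid
  S0 <- normalize_window(source$values, params$hu_window)
  T0 <- normalize_window(target$values, params$hu_window)
  alpha2 <- params$smoothness_weight^2
  n_outer <- ceiling(params$iterations_per_level / params$inner_iterations)

  u <- NULL        # list(ux, uy, uz) in mm on the current level grid
  ugrid <- NULL
  level_log <- list()
  for (lev in seq_len(params$pyramid_levels)) {
    f <- 2L^(params$pyramid_levels - lev)
    if (f == 1L && params$presmooth_sigma > 0) {
      Sl <- pyramid_level(gauss_smooth(S0, rep(params$presmooth_sigma, 3L),
                                       renormalize = TRUE), grid, 1L)
      Tl <- pyramid_level(gauss_smooth(T0, rep(params$presmooth_sigma, 3L),
                                       renormalize = TRUE), grid, 1L)
    } else {
      Sl <- pyramid_level(S0, grid, f)
      Tl <- pyramid_level(T0, grid, f)
    }
    lgrid <- Sl$grid
    shp <- lgrid$shape
    dimv <- as.integer(shp)
    if (is.null(u)) {
      uv <- list(array(0, shp), array(0, shp), array(0, shp))
    } else {
      # resample the coarser field (mm, world-anchored) onto this level
      pts_idx <- world_to_index(ugrid, voxel_centers(lgrid))
      uv <- lapply(u, function(comp)
        array(sample_trilinear_index(comp, ugrid$shape, pts_idx,
                                     clamp = TRUE), shp))
    }
    # work in voxel units at this level
    uvx <- uv[[1]] / lgrid$spacing[1]
    uvy <- uv[[2]] / lgrid$spacing[2]
    uvz <- uv[[3]] / lgrid$spacing[3]
    ia <- index_arrays(shp)
    iters_used <- 0L
    tol_vox <- params$convergence_tol / mean(lgrid$spacing)
    for (outer in seq_len(n_outer)) {
      pts <- cbind(as.vector(ia$x + uvx), as.vector(ia$y + uvy),
                   as.vector(ia$z + uvz))
      Sw <- array(sample_trilinear_index(Sl$values, dimv, pts, clamp = TRUE),
                  shp)
      # symmetric gradient: keeps a restoring force where the warped source
      # has drifted past the target edge into a flat region
      grS <- central_gradient(Sw)
      grT <- central_gradient(Tl$values)
      gr <- list(gx = (grS$gx + grT$gx) / 2, gy = (grS$gy + grT$gy) / 2,
                 gz = (grS$gz + grT$gz) / 2)
      it0 <- Sw - Tl$values
      b <- it0 - (gr$gx * uvx + gr$gy * uvy + gr$gz * uvz)
      res <- cpp_hs(as.numeric(gr$gx), as.numeric(gr$gy), as.numeric(gr$gz),
                    as.numeric(b), dimv,
                    as.numeric(uvx), as.numeric(uvy), as.numeric(uvz),
                    alpha2, params$inner_iterations, tol_vox,
                    params$sor_omega)
      uvx_new <- array(res$u, shp)
      uvy_new <- array(res$v, shp)
      uvz_new <- array(res$w, shp)
      if (params$update_smoothing_sigma > 0) {
        sg <- params$update_smoothing_sigma / lgrid$spacing
        uvx_new <- gauss_smooth(uvx_new, sg, renormalize = TRUE)
        uvy_new <- gauss_smooth(uvy_new, sg, renormalize = TRUE)
        uvz_new <- gauss_smooth(uvz_new, sg, renormalize = TRUE)
      }
      delta <- mean(abs(uvx_new - uvx) + abs(uvy_new - uvy) +
                    abs(uvz_new - uvz)) / 3
      uvx <- uvx_new; uvy <- uvy_new; uvz <- uvz_new
      iters_used <- iters_used + res$iterations
      if (delta < tol_vox) break
    }
    u <- list(uvx * lgrid$spacing[1], uvy * lgrid$spacing[2],
              uvz * lgrid$spacing[3])
    ugrid <- lgrid
    level_log[[lev]] <- tibble(level = lev, factor = f,
                               nx = shp[1], ny = shp[2], nz = shp[3],
                               iterations = iters_used)
  }

  dvf <- vector_field(u[[1]], u[[2]], u[[3]], grid)
  warped <- warp_volume(source, dvf)
  cc_pre <- cross_correlation(source, target)
  cc_post <- cross_correlation(warped, target)
  if (cc_post < cc_pre)
    warn(sprintf(
      "registration did not improve cross-correlation (%.4f -> %.4f)",
      cc_pre, cc_post))
  structure(list(dvf = dvf, warped_source = warped,
                 cross_correlation_pre = cc_pre,
                 cross_correlation_post = cc_post,
                 levels = dplyr::bind_rows(level_log),
                 params = params),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  mag <- sqrt(x$dvf$ux^2 + x$dvf$uy^2 + x$dvf$uz^2)
  cat(sprintf(
    "<registration_result> cross-correlation %.4f -> %.4f; |u| mean %.2f mm, max %.2f mm\n",
    x$cross_correlation_pre, x$cross_correlation_post, mean(mag), max(mag)))
  print(x$levels)
  invisible(x)
}

# Warp any scalar volume through a pull-back field; the out-of-grid policy
# follows the volume unit (clamp for HU, zero for dose).
warp_volume <- function(vol, dvf) {
  check_same_grid(vol, dvf, "volume and field")
  pts <- voxel_centers(vol$grid) +
    cbind(as.vector(dvf$ux), as.vector(dvf$uy), as.vector(dvf$uz))
  vals <- sample_trilinear(vol, pts)
  scalar_volume(array(vals, dim = vol$grid$shape), vol$grid, unit = vol$unit)
}

#' Voxel-wise difference map between two volumes
#'
#' Used both for registration quality assessment (HU difference of warped
#' source vs target) and for dose comparison (see [dose_difference_map()]).
#'
#' @param a,b [scalar_volume()] objects on the same grid with the same unit.
#' @return A [scalar_volume()] of `a - b` in the shared unit
#'   (`dimensionless` result is used for HU differences as they may be
#'   negative).
#' @export
difference_map <- function(a, b) {
  stopifnot(inherits(a, "scalar_volume"), inherits(b, "scalar_volume"))
  check_same_grid(a, b, "difference-map inputs")
  if (!identical(a$unit, b$unit))
    abort("difference map requires matching units")
  structure(list(values = a$values - b$values, grid = a$grid, unit = a$unit),
            class = "scalar_volume")
}

#' Pearson cross-correlation between two volumes
#'
#' @param a,b [scalar_volume()] objects on the same grid.
#' @param roi Optional [structure_mask()] restricting the comparison.
#' @return Scalar in `[-1, 1]`.
#' @export
cross_correlation <- function(a, b, roi = NULL) {
  stopifnot(inherits(a, "scalar_volume"), inherits(b, "scalar_volume"))
  check_same_grid(a, b, "cross-correlation inputs")
  if (!is.null(roi)) {
    check_same_grid(a, roi, "volume and ROI")
    va <- a$values[roi$member]
    vb <- b$values[roi$member]
  } else {
    va <- as.numeric(a$values)
    vb <- as.numeric(b$values)
  }
  if (length(va) < 2L) abort("cross-correlation needs at least 2 voxels")
  if (sd(va) == 0 || sd(vb) == 0)
    abort("constant image: cross-correlation undefined")
  cor(va, vb)
}
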