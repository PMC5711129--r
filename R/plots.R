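#' Plot a cumulative DVH curve
#'
#' @param object A [compute_dvh()] curve.
#' @param ... Additional curves to overlay, named by legend label.
#' @return A ggplot.
#' @export
autoplot.dvh_curve <- function(object, ...) {
  extra <- list(...)
  curves <- c(list(object), extra[vapply(extra, inherits, logical(1),
                                         "dvh_curve")])
  labels <- names(curves)
  if (is.null(labels)) labels <- rep("", length(curves))
  labels[labels == ""] <- vapply(curves[labels == ""], attr, character(1),
                                 "structure")
  df <- dplyr::bind_rows(lapply(seq_along(curves), function(i)
    dplyr::mutate(tidy(curves[[i]]), curve = labels[i])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = 100 * .data$fraction,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' DVH comparison plot for a study report
#'
#' Overlays the static 3D and accumulated 4D DVH of the PTV and normal
#' liver, the package's analogue of the usual 3D-vs-4D DVH figure.
#'
#' @param object A [run_study()] report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.study_report <- function(object, ...) {
  bw <- object$config$bin_width
  curves <- list(
    `PTV 3D` = compute_dvh(object$doses$static, object$masks$PTV, bw),
    `PTV 4D` = object$subset_dvhs$p10$PTV,
    `normal liver 3D` = compute_dvh(object$doses$static,
                                    object$masks$normal_liver, bw),
    `normal liver 4D` = object$subset_dvhs$p10$normal_liver)
  df <- dplyr::bind_rows(lapply(names(curves), function(nm)
    dplyr::mutate(tidy(curves[[nm]]), curve = nm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = 100 * .data$fraction,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = NULL,
                  title = "Static 3D vs accumulated 4D DVH") +
    ggplot2::theme_minimal()
}

#' Plot an axial/coronal/sagittal slice of a volume
#'
#' @param vol A [scalar_volume()].
#' @param slice 1-based slice index along `axis`; defaults to the middle.
#' @param axis Axis perpendicular to the slice: 3 = SI (axial view).
#' @param mask Optional [structure_mask()] whose boundary-ish voxels are
#'   overlaid.
#' @return A ggplot raster.
#' @export
plot_dose_slice <- function(vol, slice = NULL, axis = 3L, mask = NULL) {
  stopifnot(inherits(vol, "scalar_volume"))
  shp <- vol$grid$shape
  slice <- slice %||% ceiling(shp[axis] / 2)
  idx <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  idx[[axis]] <- slice
  plane <- do.call(`[`, c(list(vol$values), idx))
  axes <- setdiff(1:3, axis)
  df <- expand.grid(
    a = vol$grid$origin[axes[1]] +
      (seq_len(shp[axes[1]]) - 1) * vol$grid$spacing[axes[1]],
    b = vol$grid$origin[axes[2]] +
      (seq_len(shp[axes[2]]) - 1) * vol$grid$spacing[axes[2]])
  df$value <- as.vector(plane)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = vol$unit) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("axis %d (mm)", axes[1]),
                  y = sprintf("axis %d (mm)", axes[2])) +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    mplane <- do.call(`[`, c(list(mask$member), idx))
    mdf <- df[as.vector(mplane), , drop = FALSE]
    p <- p + ggplot2::geom_point(data = mdf,
                                 ggplot2::aes(x = .data$a, y = .data$b),
                                 inherit.aes = FALSE,
                                 size = 0.1, alpha = 0.25, colour = "white")
  }
  p
}
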