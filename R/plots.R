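# ggplot2 visualization helpers.

image_df <- function(image, pixel_mm = 3) {
  shape <- dim(image)
  tibble::tibble(
    x = rep(grid_axis(shape[2], pixel_mm), each = shape[1]),
    y = rep(rev(grid_axis(shape[1], pixel_mm)), shape[2]),
    value = as.vector(image))
}

#' Plot an image matrix in physical coordinates
#'
#' @param image matrix.
#' @param pixel_mm pixel size, mm.
#' @param title optional title.
#' @return a ggplot.
#' @export
plot_image <- function(image, pixel_mm = 3, title = NULL) {
  df <- image_df(image, pixel_mm)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "x (mm)", y = "y (mm)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a line profile (or several)
#'
#' @param profiles a tibble from [line_profile()], or a named list of them.
#' @return a ggplot.
#' @export
plot_profile <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profile = profiles)
  df <- dplyr::bind_rows(profiles, .id = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$distance_mm, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (mm)", y = "value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' K1 maps of a motion-correction study
#'
#' Shows the ST map plus the first-realization GA / NMC / MC maps.
#'
#' @param object a `pet_mc_study`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pet_mc_study <- function(object, ...) {
  h <- object$phantom$pixel_size
  maps <- c(list(ST = object$st_k1_map),
            lapply(object$k1_maps, function(x) x[[1]]))
  df <- dplyr::bind_rows(lapply(maps, image_df, pixel_mm = h),
                         .id = "study")
  df$study <- factor(df$study, levels = c("ST", "GA", "NMC", "MC"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85",
                                  limits = c(0, NA)) +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~study, nrow = 1) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  fill = expression(K[1])) +
    ggplot2::theme_minimal()
}

#' ROI bias and variability summary plot
#'
#' @param study a `pet_mc_study`.
#' @return a ggplot of ROI-mean K1 with SD error bars per study.
#' @export
plot_roi_summary <- function(study) {
  df <- study$roi_summary
  df$study <- factor(df$study, levels = c("ST", "GA", "NMC", "MC"))
  ggplot2::ggplot(df, ggplot2::aes(.data$roi, .data$mean_K1,
                                   fill = .data$study)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_K1 - .data$sd_K1,
                   ymax = .data$mean_K1 + .data$sd_K1),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::labs(x = NULL, y = expression(bar(K)[1] %+-% sigma),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
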