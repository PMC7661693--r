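#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

mip_plot_data <- function(pixels, pixel_size_mm, offset_mm = 0) {
  d <- dim(pixels)
  tibble::tibble(
    x_mm = rep((seq_len(d[1]) - 0.5) * pixel_size_mm[1], times = d[2]),
    z_mm = rep((seq_len(d[2]) - 0.5) * pixel_size_mm[2] + offset_mm,
               each = d[1]),
    intensity = as.vector(pixels)
  )
}

#' Plot a coronal MIP
#'
#' @param object An `mra_mip`.
#' @param ... Unused.
#' @return A ggplot (grey-scale raster, feet at the bottom).
#' @export
autoplot.mra_mip <- function(object, ...) {
  df <- mip_plot_data(object$pixels, object$pixel_size_mm,
                      object$table_offset_mm)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$z_mm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "L-R (mm)", y = "F-H (mm)",
                  title = sprintf("Coronal MIP (%s, %s)", object$method,
                                  object$station_label)) +
    ggplot2::theme_minimal()
}

#' Plot a stitched panorama
#'
#' @param object An `mra_panorama`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mra_panorama <- function(object, ...) {
  df <- mip_plot_data(object$pixels, object$pixel_size_mm)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$z_mm,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "L-R (mm)", y = "F-H (mm)",
                  title = sprintf("Stitched panorama (%s), %.0f mm F-H",
                                  object$method, object$extent_fh_mm)) +
    ggplot2::theme_minimal()
}

#' Compare VBC distributions between reconstruction methods
#'
#' @param vbc A VBC tibble (e.g. `tidy()` of an `mra_study`).
#' @return A ggplot boxplot of VBC per station and method.
#' @export
plot_vbc <- function(vbc) {
  stopifnot(all(c("method", "vbc") %in% names(vbc)))
  x_var <- if ("station_label" %in% names(vbc)) "station_label" else "method"
  ggplot2::ggplot(vbc, ggplot2::aes(.data[[x_var]], .data$vbc,
                                    fill = .data$method)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::labs(x = NULL, y = "vessel-to-background contrast") +
    ggplot2::theme_minimal()
}

#' @rdname run_study
#' @param object An `mra_study`.
#' @export
autoplot.mra_study <- function(object, ...) plot_vbc(object$vbc)
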