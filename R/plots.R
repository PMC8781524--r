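#' Plot a B-scan pair
#'
#' Side-by-side intensity (log-compressed, 60-dB range) and retardation maps
#' as depth-versus-lateral-position rasters.
#'
#' @param object A `psoct_bscan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psoct_bscan <- function(object, ...) {
  cfg <- object$config
  to_df <- function(m, channel) {
    tibble(
      depth_um = rep((seq_len(nrow(m)) - 1) * cfg$axial_pixel_spacing_um,
                     times = ncol(m)),
      lateral_um = rep((seq_len(ncol(m)) - 1) * cfg$lateral_pixel_spacing_um,
                       each = nrow(m)),
      value = as.vector(m),
      channel = channel
    )
  }
  df <- dplyr::bind_rows(
    to_df(log_compress(object$intensity), "intensity (log10)"),
    to_df(object$retardation, "retardation (deg)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral_um, .data$depth_um,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = "lateral position (um)", y = "optical depth (um)") +
    ggplot2::theme_minimal()
}

#' Plot a laterally averaged retardation profile
#'
#' @param object A [lateral_average()] result.
#' @param estimate Optional [fit_birefringence()] result; when given, the
#'   fitted line is overlaid on its fit window.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psoct_profile <- function(object, estimate = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(.data$depth_um, .data$retardation_deg)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(
      x = "physical depth below surface (um)",
      y = "mean retardation (deg)",
      subtitle = sprintf("%d columns averaged", attr(object, "n_columns"))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(estimate)) {
    w <- estimate$fit_window_um
    fitdf <- tibble(
      depth_um = w,
      retardation_deg = estimate$intercept_deg + estimate$slope_deg_per_um * w
    )
    p <- p + ggplot2::geom_line(data = fitdf, colour = "red", linewidth = 0.8)
  }
  p
}

#' Plot a stretch-characterization curve
#'
#' Mean induced birefringence versus length ratio with replicate-sd error
#' bars, in the style of a slab-phantom characterization figure.
#'
#' @param object A [build_characterization_curve()] result (a `psoct_curve`),
#'   or several row-bound together (one colour per curing ratio).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psoct_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    .data$length_ratio, .data$mean_delta_n,
    colour = factor(.data$curing_ratio),
    group = factor(.data$curing_ratio)
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_delta_n - .data$sd_delta_n,
      ymax = .data$mean_delta_n + .data$sd_delta_n
    ), width = 0.05) +
    ggplot2::labs(
      x = "length ratio (elongated / original)",
      y = expression(paste("induced birefringence ", Delta * n)),
      colour = "curing ratio"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
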