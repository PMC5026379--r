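# ggplot2 graphics for the package's result classes.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot venous serum concentration curves
#'
#' @param sim A `hepapk_pbpk` or `hepapk_multiscale` result.
#' @param ref Optional reference ADME table plotted as open symbols.
#' @param unit `"ug_per_mL"` (default) or `"mmol_per_L"`.
#' @return A ggplot.
#' @export
plot_serum_curves <- function(sim, ref = NULL, unit = "ug_per_mL") {
  ser <- serum_concentrations(sim)
  ycol <- if (unit == "ug_per_mL") "conc_ug_per_mL" else "conc_mmol_per_L"
  p <- ggplot2::ggplot(ser, ggplot2::aes(x = .data$time_h,
                                         y = .data[[ycol]],
                                         colour = .data$compound)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)",
                  y = if (unit == "ug_per_mL") "serum concentration (µg/mL)"
                  else "serum concentration (mmol/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(ref)) {
    ref2 <- ref
    if (unit == "ug_per_mL") {
      mm <- hepapk_molar_masses()
      conv <- ifelse(ref2$unit == "mmol_per_L", mm[ref2$compound], 1)
      ref2$concentration <- ref2$concentration * conv
    }
    p <- p + ggplot2::geom_point(
      data = ref2,
      ggplot2::aes(x = .data$time_h, y = .data$concentration,
                   colour = .data$compound),
      shape = 1, size = 2, inherit.aes = FALSE)
  }
  p
}

#' @export
autoplot.hepapk_pbpk <- function(object, ...) plot_serum_curves(object, ...)

#' @export
autoplot.hepapk_multiscale <- function(object, ...) {
  plot_serum_curves(object, ...)
}

#' @export
autoplot.hepapk_subcell <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h,
                                       y = .data$conc_mmol_per_L,
                                       colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "concentration (mmol/L)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heat-map of a sensitivity matrix
#' @param object A `hepapk_sensitivity` object.
#' @param ... Unused.
#' @export
autoplot.hepapk_sensitivity <- function(object, ...) {
  long <- tidy(object)
  long$output <- factor(long$output, levels = rev(rownames(object$matrix)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$output,
                                     fill = abs(.data$sensitivity))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "|J|", na.value = "grey80") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Population mean curves with variability ribbons
#' @param object A `hepapk_population` object.
#' @param ... Unused.
#' @export
autoplot.hepapk_population <- function(object, ...) {
  sc <- object$summary_curves
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$time_h, y = .data$mean_conc,
                                   colour = .data$compound,
                                   fill = .data$compound)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean_conc -
                                                    .data$sd_conc, 0),
                                      ymax = .data$mean_conc +
                                        .data$sd_conc),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (h)", y = "serum concentration (mmol/L)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Space-time heat map of a sinusoid pulse experiment
#' @param object A `hepapk_pulse` tibble.
#' @param compound Compound to display.
#' @param ... Unused.
#' @export
autoplot.hepapk_pulse <- function(object, compound = "APAP", ...) {
  df <- object[object$compound == compound, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um, y = .data$time_s,
                                   colour = .data$conc_mmol_per_L,
                                   shape = .data$entity_type)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_colour_viridis_c(name = "mmol/L") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "axial position (µm)", y = "time (s)") +
    ggplot2::theme_minimal()
}

#' Zonal concentration summary plot
#' @param zs Output of [zonal_summary()].
#' @param species Species to display (default `"NAPQI_GSH"`).
#' @return A ggplot.
#' @export
plot_zonal <- function(zs, species = "NAPQI_GSH") {
  df <- zs[zs$species == species, ]
  df$zone <- factor(df$zone, levels = c("PP", "MZ", "PV"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$mean_conc,
                                   colour = .data$zone)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_conc - .data$sd_conc,
                                      ymax = .data$mean_conc + .data$sd_conc,
                                      fill = .data$zone),
                         alpha = 0.15, colour = NA) +
    ggplot2::labs(x = "time (h)", y = paste(species, "(mmol/L)"),
                  colour = "zone", fill = "zone") +
    ggplot2::theme_minimal()
}
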