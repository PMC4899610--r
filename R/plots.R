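# ggplot2 autoplot methods for the package's result types.

#' @describeIn as_spectral_series Plot absorbance against time, one line
#'   per recorded wavelength.
#' @param object,... Autoplot object and unused arguments.
#' @export
autoplot.spectral_series <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_min, y = .data$absorbance,
                               colour = factor(.data$wavelength_nm))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Absorbance (AU)",
                  colour = "Wavelength (nm)")
}

#' @describeIn kinetic_trace Plot the concentration trace in uM.
#' @param object,... Autoplot object and unused arguments.
#' @export
autoplot.kinetic_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time_min,
                               y = .data$concentration_M * 1e6)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (min)", y = "Concentration (uM)",
                  title = unique(object$species)[1])
}

#' @describeIn simulate_peroxidation Plot every species trajectory on a
#'   log concentration axis, faceted by species.
#' @param object Autoplot object.
#' @export
autoplot.peroxidation_sim <- function(object, ...) {
  long <- tidy(object)
  long <- long[long$species != "quenched", ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_min,
                                     y = .data$concentration_M)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "Time (min)", y = "Concentration (M)")
}

#' @describeIn build_metrics_table Bar chart of inhibited oxidation
#'   rates with replicate sd error bars (log axis: efficiencies span two
#'   orders of magnitude).
#' @param object,... Autoplot object and unused arguments.
#' @export
autoplot.peroxidation_metrics <- function(object, ...) {
  df <- as_tibble(object)
  df$antioxidant <- factor(df$antioxidant, levels = df$antioxidant)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$antioxidant,
                                   y = .data$rate_nM_min)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = pmax(.data$rate_nM_min - .data$rate_sd_nM_min, 1e-3),
      ymax = .data$rate_nM_min + .data$rate_sd_nM_min), width = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "CL oxidation rate (nM/min, log scale)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
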