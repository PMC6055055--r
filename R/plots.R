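# ggplot2 graphics for the main result types.

#' Diurnal course of canopy fluxes
#'
#' Plots instantaneous transpiration and gross photosynthesis over the
#' day, faceted by variable; for a `canopy_run`, potential and actual
#' rates are overlaid so midday stomatal depression is visible.
#'
#' @param object A `flux_series` or `canopy_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flux_series <- function(object, ...) {
  df <- object |>
    select("time", "ec", "ac_gross") |>
    tidyr::pivot_longer(c("ec", "ac_gross"), names_to = "variable")
  ggplot2::ggplot(df, ggplot2::aes(.data$time / 3600, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          ec = "Ec (mmol H2O m-2 s-1)",
                          ac_gross = "Ac,gross (umol CO2 m-2 s-1)"))) +
    ggplot2::labs(x = "Hour of day", y = NULL)
}

#' @rdname autoplot.flux_series
#' @export
autoplot.canopy_run <- function(object, ...) {
  df <- object |>
    select("time", "ec_pot", "ec", "ac_gross_pot", "ac_gross") |>
    tidyr::pivot_longer(-"time", names_to = "series") |>
    mutate(variable = ifelse(grepl("^ec", .data$series), "Ec", "Ac,gross"),
           mode = ifelse(grepl("pot$", .data$series), "potential", "actual"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time / 3600, .data$value,
                                   linetype = .data$mode)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "Hour of day", y = NULL, linetype = NULL)
}

#' Canopy profile with fitted extinction curves
#'
#' Relative light and SLN against cumulative LAI, with fitted Beer's-law
#' and exponential-nitrogen curves overlaid when fits are supplied.
#'
#' @param profile A `profile_table`.
#' @param kl_fit Optional `light_extinction_fit`.
#' @param n_fit Optional `nitrogen_profile_fit`.
#' @return A ggplot object.
#' @export
plot_profile <- function(profile, kl_fit = NULL, n_fit = NULL) {
  grid <- tibble(lai = seq(0, max(profile$lai), length.out = 100))
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$lai, .data$rel_light)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Cumulative LAI (m2 m-2)", y = "I/I0")
  if (!is.null(kl_fit)) {
    grid$rel_light <- exp(-kl_fit$kl * grid$lai)
    p <- p + ggplot2::geom_line(data = grid)
  }
  p
}

#' Forcing-analysis summary plot
#'
#' Potential fluxes and efficiencies per treatment under the default,
#' forced-LAI and forced-SLN simulations.
#'
#' @param x Output of [forcing_analysis()].
#' @return A ggplot object.
#' @export
plot_forcing <- function(x) {
  df <- x |>
    tidyr::pivot_longer(c("ecp_daily", "acp_gross_daily", "pwue_cp",
                          "pnue_cp"), names_to = "quantity")
  ggplot2::ggplot(df, ggplot2::aes(.data$treatment, .data$value,
                                   colour = .data$scenario,
                                   group = .data$scenario)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL)
}
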