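# Model-based normalization of chamber-measured fluxes to open-air
# conditions. The chamber wall changes temperature, vapour pressure, CO2
# and light; the canopy model run under the two micro-environments yields
# multiplicative correction factors per record.

#' Transpiration correction factor between open-air and chamber weather
#'
#' `f_Ec = Ecp_air / Ecp_chamber`: the ratio of simulated potential canopy
#' transpiration under open-air weather to that under in-chamber weather,
#' per record. Multiplying chamber-measured transpiration by `f_Ec`
#' expresses it at open-air conditions. At night, when potential
#' transpiration is negligible, the factor is set to 1 and flagged.
#'
#' @param canopy A [canopy_state()].
#' @param weather_air,weather_chamber Open-air and in-chamber
#'   `weather_series` on the same time grid.
#' @param params A [leaf_params()].
#' @param night_ec Potential-transpiration threshold below which a record
#'   counts as night, mmol m^-2 s^-1.
#' @param ... Passed to [canopy_gas_exchange()].
#' @return A tibble: `time`, `f_ec`, `night`, plus the simulated
#'   `ecp_air`, `ecp_chamber`.
#' @export
compute_f_ec <- function(canopy, weather_air, weather_chamber,
                         params = leaf_params(), night_ec = 0.05, ...) {
  check_same_grid(weather_air, weather_chamber)
  run_air <- canopy_gas_exchange(canopy, weather_air, params, ...)
  run_ch <- canopy_gas_exchange(canopy, weather_chamber, params, ...)
  night <- run_ch$ec_pot < night_ec | run_air$ec_pot < night_ec
  f <- ifelse(night, 1, run_air$ec_pot / run_ch$ec_pot)
  tibble(time = weather_air$time, f_ec = f, night = night,
         ecp_air = run_air$ec_pot, ecp_chamber = run_ch$ec_pot)
}

#' Photosynthesis correction factor between open-air and chamber weather
#'
#' `f_Ac = Ac,gross,air(s) / Ac,gross,chamber(s)`: the ratio of simulated
#' water-limited gross canopy photosynthesis under open-air weather
#' (driven by the corrected transpiration `Ec x f_Ec`) to that under
#' chamber weather (driven by the measured `Ec`). Both simulations use the
#' water-limited model, so under ample water the two collapse to the
#' potential ratio.
#'
#' @param canopy A [canopy_state()].
#' @param ec_corrected Corrected (open-air equivalent) transpiration per
#'   record, mmol m^-2 s^-1.
#' @param ec_measured Measured chamber transpiration per record.
#' @param weather_air,weather_chamber As in [compute_f_ec()].
#' @param params A [leaf_params()].
#' @param night_ac Gross-photosynthesis threshold for the night flag,
#'   umol m^-2 s^-1.
#' @param ... Passed to [canopy_gas_exchange()].
#' @return A tibble: `time`, `f_ac`, `night`, `ac_air`, `ac_chamber`.
#' @export
compute_f_ac <- function(canopy, ec_corrected, ec_measured,
                         weather_air, weather_chamber,
                         params = leaf_params(), night_ac = 0.5, ...) {
  check_same_grid(weather_air, weather_chamber)
  stopifnot(length(ec_corrected) == nrow(weather_air),
            length(ec_measured) == nrow(weather_chamber))
  run_air <- canopy_gas_exchange(canopy, weather_air, params,
                                 water = pmax(ec_corrected, 1e-6), ...)
  run_ch <- canopy_gas_exchange(canopy, weather_chamber, params,
                                water = pmax(ec_measured, 1e-6), ...)
  night <- run_ch$ac_gross < night_ac | run_air$ac_gross < night_ac
  f <- ifelse(night, 1, run_air$ac_gross / run_ch$ac_gross)
  tibble(time = weather_air$time, f_ac = f, night = night,
         ac_air = run_air$ac_gross, ac_chamber = run_ch$ac_gross)
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$time != b$time)) {
    abort("weather series must share the same time grid")
  }
  invisible(TRUE)
}

#' Apply correction factors to a flux series
#'
#' Multiplies measured transpiration by `f_ec` and gross photosynthesis by
#' `f_ac`, record by record. Night records (factor flagged) pass through
#' unchanged; records without a matching factor are flagged and left
#' unchanged.
#'
#' @param flux A `flux_series` from [compute_fluxes()].
#' @param factors A data frame with `time`, `f_ec` and/or `f_ac` (e.g. a
#'   join of [compute_f_ec()] and [compute_f_ac()] output).
#' @return The flux series with `ec` and `ac_gross` normalized and a
#'   logical `normalized` column.
#' @export
normalize_series <- function(flux, factors) {
  fac <- factors |> select(dplyr::any_of(c("time", "f_ec", "f_ac")))
  out <- flux |> left_join(fac, by = "time")
  if (!"f_ec" %in% names(out)) out$f_ec <- NA_real_
  if (!"f_ac" %in% names(out)) out$f_ac <- NA_real_
  out |>
    mutate(normalized = !is.na(.data$f_ec) | !is.na(.data$f_ac),
           ec = .data$ec * dplyr::coalesce(.data$f_ec, 1),
           ac_gross = .data$ac_gross * dplyr::coalesce(.data$f_ac, 1)) |>
    select(-"f_ec", -"f_ac") |>
    structure(class = c("flux_series", class(tibble())))
}
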