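# Synthetic-data generators. Every generator is seed-deterministic and has
# known ground truth so the downstream flux arithmetic, fits and model
# stages can be tested without access to the original logger records.

#' Generate a diurnal weather series
#'
#' Builds an open-air micro-environment time series for one day: PAR follows
#' solar elevation scaled to a peak value (zero at night), air temperature
#' and vapour pressure are smooth diurnal curves (sinusoid with an afternoon
#' lag), and CO2 mirrors temperature (drawdown during the day). Defaults
#' emulate a clear mid-summer day at a mid-latitude lowland site: peak PAR
#' 2100 umol m^-2 s^-1, air temperature 17.6-35.9 degC, vapour pressure
#' 1.7-2.5 kPa and CO2 359.7-439.4 umol mol^-1.
#'
#' @param latitude Latitude, degrees.
#' @param day_of_year Day of year.
#' @param cadence_s Record cadence in seconds; must divide 86400.
#' @param par_peak Maximum incident PAR, umol m^-2 s^-1.
#' @param t_range Length-2 numeric, daily min/max air temperature, degC.
#' @param vp_range Length-2 numeric, daily min/max vapour pressure, kPa.
#' @param co2_range Length-2 numeric, daily min/max CO2, umol mol^-1 (the
#'   maximum occurs at night, the minimum mid-afternoon).
#' @param wind Wind speed, m s^-1 (constant).
#' @param p_atm Air pressure, kPa.
#' @param noise_sd Named list of additive Gaussian noise SDs for
#'   `par`, `t_air`, `vp`, `co2` (defaults all 0).
#' @param lag_h Hours after solar noon at which temperature peaks.
#' @param seed Integer seed; the series is reproducible given the seed.
#' @return A tibble (`weather_series`) with columns `time`, `par`, `t_air`,
#'   `co2`, `vp`, `wind`, `p_atm`.
#' @examples
#' w <- generate_weather(seed = 1)
#' range(w$par)
#' @export
generate_weather <- function(latitude = 45.0, day_of_year = 180,
                             cadence_s = 720, par_peak = 2100,
                             t_range = c(17.6, 35.9),
                             vp_range = c(1.7, 2.5),
                             co2_range = c(359.7, 439.4),
                             wind = 0.5, p_atm = cf_constants$P_std,
                             noise_sd = list(), lag_h = 2, seed = 1) {
  if (86400 %% cadence_s != 0) {
    abort("generate_weather: cadence_s must divide 86400")
  }
  stopifnot(par_peak >= 0, wind >= 0, p_atm > 0,
            diff(t_range) >= 0, diff(vp_range) >= 0, diff(co2_range) >= 0)
  ns <- list(par = 0, t_air = 0, vp = 0, co2 = 0)
  ns[names(noise_sd)] <- noise_sd
  if (any(unlist(ns) < 0)) abort("generate_weather: noise SDs must be >= 0")

  time <- seq(0, 86400 - cadence_s, by = cadence_s)
  sol <- solar_position(time, latitude, day_of_year)
  sb_max <- max(sol$sin_beta)
  if (sb_max <= 0) abort("generate_weather: sun never rises for this latitude/day")

  # diurnal phase peaking lag_h after solar noon
  phase <- cos(2 * pi * (time / 3600 - 12 - lag_h) / 24)
  frac <- (phase + 1) / 2
  withr_seed(seed, {
    par <- par_peak * pmax(sol$sin_beta, 0) / sb_max +
      rnorm(length(time), 0, ns$par)
    t_air <- t_range[1] + diff(t_range) * frac +
      rnorm(length(time), 0, ns$t_air)
    vp <- vp_range[1] + diff(vp_range) * frac +
      rnorm(length(time), 0, ns$vp)
    co2 <- co2_range[2] - diff(co2_range) * frac +
      rnorm(length(time), 0, ns$co2)
  })
  par <- pmax(par, 0)
  vp <- pmin(pmax(vp, 0), svp(t_air))
  out <- tibble(time = time, par = par, t_air = t_air, co2 = co2, vp = vp,
                wind = wind, p_atm = p_atm)
  class(out) <- c("weather_series", class(out))
  attr(out, "latitude") <- latitude
  attr(out, "day_of_year") <- day_of_year
  out
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulate chamber logger records from known true fluxes
#'
#' Inverts the flow-through chamber mass balance: given true canopy
#' transpiration `ec` (mmol H2O m^-2 s^-1) and net photosynthesis `ac_net`
#' (umol CO2 m^-2 s^-1), writes the vapour-pressure and CO2 differentials a
#' logger would record, so that [compute_ec()] / [compute_ac_net()] recover
#' the true fluxes exactly on noiseless output. Gaussian noise, when
#' requested, is added on the logger signals (not on the derived fluxes),
#' mimicking instrument error.
#'
#' @param weather A `weather_series` giving entrance conditions (`co2`,
#'   `vp`, `t_air`); its time grid must match `true_flux`.
#' @param true_flux A data frame with columns `time`, `ec`, `ac_net`.
#' @param cfg A [system_config()].
#' @param chamber_id Chamber identifier written to the records.
#' @param dt_offset Radiative chamber warming added to `t_dif`, degC
#'   (scaled by relative PAR during the day).
#' @param noise_sd Named list of additive Gaussian SDs for `co2_dif`
#'   (umol mol^-1), `vp_dif` (kPa), `t_dif` (degC); defaults all 0.
#' @param seed Integer seed.
#' @return A tibble (`chamber_series`) with logger columns `time`,
#'   `chamber_id`, `co2_in`, `co2_dif`, `vp_in`, `vp_dif`, `t_in`, `t_dif`,
#'   `w_container`, `radiation`.
#' @export
simulate_chamber_series <- function(weather, true_flux, cfg = system_config(),
                                    chamber_id = "C01", dt_offset = 0,
                                    noise_sd = list(), seed = 1) {
  stopifnot(inherits(cfg, "system_config"))
  if (!all(c("time", "ec", "ac_net") %in% names(true_flux))) {
    abort("simulate_chamber_series: true_flux needs columns time, ec, ac_net")
  }
  if (nrow(weather) != nrow(true_flux) ||
      any(weather$time != true_flux$time)) {
    abort("simulate_chamber_series: weather and true_flux time grids differ")
  }
  ns <- list(co2_dif = 0, vp_dif = 0, t_dif = 0)
  ns[names(noise_sd)] <- noise_sd

  u_e <- cfg$u_e; a <- cfg$a; p <- cfg$p
  ec <- true_flux$ec; ac <- true_flux$ac_net
  # Ec = 1000 u_e VPdif / (a (P - VPin - VPdif))  =>  solve for VPdif
  vp_dif <- ec * a * (p - weather$vp) / (1000 * u_e + ec * a)
  # Ac,net = -(u_e CO2dif / a + 1e-3 Ec CO2out), CO2out = CO2in + CO2dif
  co2_dif <- -(ac + 1e-3 * ec * weather$co2) / (u_e / a + 1e-3 * ec)
  rel_par <- if (max(weather$par) > 0) weather$par / max(weather$par) else 0
  t_dif <- dt_offset * rel_par

  withr_seed(seed, {
    co2_dif <- co2_dif + rnorm(length(ec), 0, ns$co2_dif)
    vp_dif <- vp_dif + rnorm(length(ec), 0, ns$vp_dif)
    t_dif <- t_dif + rnorm(length(ec), 0, ns$t_dif)
  })
  out <- tibble(
    time = weather$time, chamber_id = chamber_id,
    co2_in = weather$co2, co2_dif = co2_dif,
    vp_in = weather$vp, vp_dif = vp_dif,
    t_in = weather$t_air, t_dif = t_dif,
    w_container = NA_real_, radiation = weather$par
  )
  class(out) <- c("chamber_series", class(out))
  out
}

#' Generate a layered canopy profile with known extinction coefficients
#'
#' Builds the per-layer records a destructive canopy sampling produces:
#' cumulative leaf area index from the top, relative light `I_i/I_0 =
#' exp(-kL LAI_i)`, specific leaf nitrogen `SLN_i = SLN0 exp(-kn LAI_i)`,
#' and cumulative leaf nitrogen from the analytic profile integral. With
#' zero noise the records satisfy all three relations exactly.
#'
#' @param sln0 Top-of-canopy specific leaf nitrogen, g N m^-2 leaf.
#' @param kn Nitrogen extinction coefficient, m^2 m^-2 (>= 0).
#' @param kl Light extinction coefficient, m^2 m^-2 (> 0).
#' @param lai_total Total canopy LAI, m^2 m^-2.
#' @param n_layers Number of measurement depths (>= 2); layer boundaries
#'   follow the canopy-height fractions of a four-height sampling scheme
#'   when `n_layers = 4`, otherwise equal LAI increments.
#' @param noise_sd Named list of multiplicative (lognormal-free, additive on
#'   the measured scale) Gaussian SDs for `rel_light` and `sln`.
#' @param seed Integer seed.
#' @return A tibble (`profile_table`) with columns `layer`, `height_frac`,
#'   `lai`, `rel_light`, `sln`, `n_cum`.
#' @export
generate_canopy_profile <- function(sln0, kn, kl, lai_total, n_layers = 4,
                                    noise_sd = list(), seed = 1) {
  if (kn < 0) abort("generate_canopy_profile: kn must be >= 0")
  if (kl <= 0) abort("generate_canopy_profile: kl must be > 0")
  stopifnot(lai_total > 0, n_layers >= 2, sln0 > 0)
  ns <- list(rel_light = 0, sln = 0)
  ns[names(noise_sd)] <- noise_sd

  if (n_layers == 4) {
    # sampling at 90, 75, 50 and 0 % of canopy height; LAI accumulates
    # roughly in proportion to depth from the top
    height_frac <- c(90, 75, 50, 0)
    lai <- lai_total * (100 - height_frac) / 100
  } else {
    height_frac <- rev(seq(0, 100, length.out = n_layers + 1))[-1]
    lai <- lai_total * seq_len(n_layers) / n_layers
  }
  rel_light <- exp(-kl * lai)
  sln <- sln0 * exp(-kn * lai)
  n_cum <- cumulative_nitrogen(lai, sln0, kn)
  withr_seed(seed, {
    rel_light <- pmax(rel_light + rnorm(n_layers, 0, ns$rel_light), 1e-4)
    sln <- pmax(sln + rnorm(n_layers, 0, ns$sln), 1e-3)
  })
  if (any(unlist(ns) > 0)) {
    # rebuild the cumulative-N record from the (noisy) layer SLNs by
    # trapezoid, as a field protocol would
    mid_sln <- (c(sln0, sln[-n_layers]) + sln) / 2
    n_cum <- cumsum(mid_sln * diff(c(0, lai)))
  }
  out <- tibble(layer = seq_len(n_layers), height_frac = height_frac,
                lai = lai, rel_light = pmin(rel_light, 1), sln = sln,
                n_cum = n_cum)
  class(out) <- c("profile_table", class(out))
  attr(out, "truth") <- list(sln0 = sln0, kn = kn, kl = kl,
                             lai_total = lai_total)
  out
}

#' Generate night-time respiration measurements
#'
#' Samples chamber air temperatures within a night-time range and evaluates
#' the exponential respiration temperature response
#' `Rc = Rc25 exp(ERc (T - 25) / (298 R (T + 273)))`, plus additive noise.
#'
#' @param rc25 Canopy respiration at 25 degC, umol CO2 m^-2 s^-1 (> 0).
#' @param erc Activation energy, J mol^-1.
#' @param t_range Length-2 night temperature range, degC; a zero-width
#'   range with `n > 1` is rejected (the fit would be unidentifiable).
#' @param n Number of samples (>= 3).
#' @param noise_sd Additive Gaussian SD on Rc, umol m^-2 s^-1.
#' @param seed Integer seed.
#' @return A tibble with columns `t_air`, `rc`.
#' @export
generate_night_respiration <- function(rc25, erc, t_range = c(14.7, 25.7),
                                       n = 100, noise_sd = 0, seed = 1) {
  stopifnot(rc25 > 0, n >= 3, noise_sd >= 0)
  if (diff(range(t_range)) <= 0 && n > 1) {
    abort("generate_night_respiration: degenerate t_range makes the fit unidentifiable")
  }
  withr_seed(seed, {
    t_air <- runif(n, t_range[1], t_range[2])
    rc <- respiration_at(t_air, respiration_params(rc25, erc)) +
      rnorm(n, 0, noise_sd)
  })
  tibble(t_air = t_air, rc = rc)
}

#' Steady-state chamber micro-climate from canopy fluxes
#'
#' Derives the in-chamber weather implied by a flow-through mass balance:
#' exit CO2 is drawn down by net photosynthesis (`dCO2 = -Ac,net a / u_e`),
#' exit vapour pressure is raised by transpiration (the exact inversion of
#' the transpiration mass balance), temperature carries a configurable
#' radiative offset, and PAR is attenuated by the top-disc transmittance.
#' Used to build chamber-vs-open-air weather pairs for normalization.
#'
#' @param weather Open-air `weather_series`.
#' @param flux A data frame with `time`, `ec`, `ac_net` (chamber fluxes).
#' @param cfg A [system_config()].
#' @param dt_offset Peak radiative warming inside the chamber, degC (scaled
#'   by relative PAR). Closed plastic enclosures in full sun run several
#'   degrees above ambient.
#' @param apply_transmittance Reduce PAR by the top-disc transmittance?
#'   Default `FALSE`: the radiation record is measured outside the
#'   chamber and enters both the chamber and open-air simulations
#'   unchanged; set `TRUE` to emulate an in-chamber light measurement.
#' @return A `weather_series` describing the in-chamber micro-environment.
#' @details The canopy inside a flow-through chamber sits between the
#'   entrance and exit air streams, so the gas offsets applied are half
#'   the exit-minus-entrance differentials implied by the mass balance.
#' @export
chamber_microclimate <- function(weather, flux, cfg = system_config(),
                                 dt_offset = 4, apply_transmittance = FALSE) {
  stopifnot(nrow(weather) == nrow(flux))
  vp_dif <- flux$ec * cfg$a * (cfg$p - weather$vp) /
    (1000 * cfg$u_e + flux$ec * cfg$a)
  co2_dif <- -(flux$ac_net + 1e-3 * flux$ec * weather$co2) /
    (cfg$u_e / cfg$a + 1e-3 * flux$ec)
  rel_par <- if (max(weather$par) > 0) weather$par / max(weather$par) else 0
  out <- weather
  out$co2 <- weather$co2 + co2_dif / 2
  out$t_air <- weather$t_air + dt_offset * rel_par
  out$vp <- pmin(weather$vp + vp_dif / 2, svp(out$t_air))
  if (apply_transmittance) out$par <- weather$par * cfg$trans_top
  out
}
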