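# Chamber flux arithmetic: QC filtering, empty-chamber baseline
# correction, the flow-through mass-balance flux equations, the night
# respiration temperature response, and daily integration.

#' Instantaneous canopy transpiration from chamber differentials
#'
#' Flow-through chamber mass balance for water vapour:
#' `Ec = 1000 u_e VPdif / (a (P - (VPin + VPdif)))`, with `Ec` in
#' mmol H2O m^-2 s^-1.
#'
#' @param vp_in Entrance vapour pressure, kPa.
#' @param vp_dif Exit-minus-entrance vapour pressure difference, kPa.
#' @param cfg A [system_config()].
#' @return Canopy transpiration, mmol H2O m^-2 s^-1 (vectorised).
#' @examples
#' compute_ec(2.0, 0.10, system_config())
#' @export
compute_ec <- function(vp_in, vp_dif, cfg = system_config()) {
  stopifnot(inherits(cfg, "system_config"))
  denom <- cfg$p - (vp_in + vp_dif)
  if (any(denom <= 0, na.rm = TRUE)) {
    abort("compute_ec: chamber pressure must exceed total vapour pressure")
  }
  1000 * cfg$u_e * vp_dif / (cfg$a * denom)
}

#' Instantaneous net canopy photosynthesis from chamber differentials
#'
#' `Ac,net = -(u_e CO2dif / a + 1e-3 Ec CO2out)` with
#' `CO2out = CO2in + CO2dif`; positive values are net CO2 uptake. The
#' second term accounts for the dilution of exit CO2 by transpired water.
#'
#' @param co2_in Entrance CO2, umol mol^-1.
#' @param co2_dif Exit-minus-entrance CO2 difference, umol mol^-1.
#' @param ec Canopy transpiration from [compute_ec()], mmol m^-2 s^-1.
#' @param cfg A [system_config()].
#' @return Net photosynthesis, umol CO2 m^-2 s^-1 (vectorised).
#' @examples
#' compute_ac_net(400, -10, ec = 0.886, system_config())
#' @export
compute_ac_net <- function(co2_in, co2_dif, ec, cfg = system_config()) {
  stopifnot(inherits(cfg, "system_config"))
  co2_out <- co2_in + co2_dif
  if (any(co2_out <= 0, na.rm = TRUE)) {
    abort("compute_ac_net: exit CO2 must be positive")
  }
  -(cfg$u_e * co2_dif / cfg$a + 1e-3 * ec * co2_out)
}

#' Flag and drop spike-contaminated chamber records
#'
#' Short-time fluctuations of entrance CO2 and vapour pressure are detected
#' per chamber with a centred rolling median: a record is rejected when
#' either signal deviates from its rolling median by more than
#' `k x 1.4826 x MAD` of the residuals. An all-constant series has zero
#' spread and no record is rejected.
#'
#' @param series A `chamber_series` tibble.
#' @param policy A [qc_policy()].
#' @return The input with a logical column `qc_keep`: rejected records stay
#'   in the table flagged `FALSE`, so both the kept and the rejected sets
#'   are available (`dplyr::filter(x, qc_keep)` / `filter(x, !qc_keep)`).
#' @export
filter_records <- function(series, policy = qc_policy()) {
  stopifnot(inherits(policy, "qc_policy"))
  if (nrow(series) == 0) abort("filter_records: empty series")
  out <- series |>
    group_by(.data$chamber_id) |>
    group_modify_keep(function(df) {
      if (policy$window > nrow(df)) {
        abort("filter_records: QC window longer than the series")
      }
      keep <- rep(TRUE, nrow(df))
      floors <- c(co2_in = policy$floor_co2, vp_in = policy$floor_vp)
      for (sig in c("co2_in", "vp_in")) {
        x <- df[[sig]]
        med <- stats::runmed(x, policy$window, endrule = "median")
        resid <- x - med
        # In slope-dominated stretches the centre record is its own
        # window median, so residuals are zero-inflated and a plain MAD
        # collapses; the robust scale comes from the nonzero deviations.
        # If almost everything sits on the median (constant signal with
        # isolated spikes) the scale is left at zero and the absolute
        # floor alone separates spikes from signal.
        nz <- resid[resid != 0]
        sd_rob <- if (length(nz) >= 0.2 * length(resid)) {
          stats::mad(nz, center = 0)
        } else 0
        keep <- keep & abs(resid) <= pmax(policy$k * sd_rob, floors[[sig]])
      }
      df$qc_keep <- keep
      df
    })
  class(out) <- unique(c("chamber_series", class(out)))
  out
}

# group_modify that preserves non-grouping columns simply
group_modify_keep <- function(gdf, f) {
  dplyr::group_modify(gdf, function(df, key) f(df)) |> dplyr::ungroup()
}

#' Correct chamber signals for leaks and soil respiration
#'
#' Empty-chamber runs (recorded after the plants were cut) carry any system
#' error from gas leakage or residual soil exchange. Their per-chamber mean
#' `co2_dif` and `vp_dif` are subtracted from the plant-run signals.
#'
#' @param series Plant-run `chamber_series`.
#' @param empty_runs Empty-chamber `chamber_series` for the same chambers.
#' @return The corrected series. Chambers without an empty run get zero
#'   correction with a warning.
#' @export
correct_baseline <- function(series, empty_runs) {
  base <- empty_runs |>
    group_by(.data$chamber_id) |>
    summarise(base_co2 = mean(.data$co2_dif, na.rm = TRUE),
              base_vp = mean(.data$vp_dif, na.rm = TRUE), .groups = "drop")
  missing <- setdiff(unique(series$chamber_id), base$chamber_id)
  if (length(missing)) {
    warn(paste0("correct_baseline: no empty run for chamber(s) ",
                paste(missing, collapse = ", "), "; zero correction applied"))
  }
  out <- series |>
    left_join(base, by = "chamber_id") |>
    mutate(base_co2 = dplyr::coalesce(.data$base_co2, 0),
           base_vp = dplyr::coalesce(.data$base_vp, 0),
           co2_dif = .data$co2_dif - .data$base_co2,
           vp_dif = .data$vp_dif - .data$base_vp) |>
    select(-"base_co2", -"base_vp")
  class(out) <- unique(c("chamber_series", class(out)))
  out
}

#' Respiration temperature-response parameters
#'
#' @param rc25 Canopy respiration at 25 degC, umol CO2 m^-2 s^-1 (>= 0).
#' @param erc Activation energy, J mol^-1.
#' @return An object of class `respiration_params`.
#' @export
respiration_params <- function(rc25, erc) {
  stopifnot(rc25 >= 0, is.finite(erc))
  structure(list(rc25 = rc25, erc = erc, r_gas = cf_constants$R_gas),
            class = "respiration_params")
}

#' Canopy respiration at a given air temperature
#'
#' Exponential (Arrhenius-type) temperature response
#' `Rc = Rc25 exp(ERc (Tair - 25) / (298 R (Tair + 273)))` with R the
#' universal gas constant.
#'
#' @param t_air Air temperature, degC (> -273); vectorised.
#' @param p A [respiration_params()].
#' @return Respiration, umol CO2 m^-2 s^-1.
#' @examples
#' respiration_at(35, respiration_params(4, 9559))
#' @export
respiration_at <- function(t_air, p) {
  stopifnot(inherits(p, "respiration_params"), all(t_air > -273))
  p$rc25 * exp(p$erc * (t_air - 25) / (298 * p$r_gas * (t_air + 273)))
}

#' Estimate the respiration temperature response from night records
#'
#' Nonlinear least-squares fit of the exponential temperature response to
#' night-time (respiration, temperature) pairs. Night is defined upstream
#' as records with incident PAR below a small threshold (5 umol m^-2 s^-1
#' in [compute_fluxes()]).
#'
#' @param night A data frame with columns `t_air` (degC) and `rc`
#'   (umol CO2 m^-2 s^-1, positive = efflux).
#' @return A `respiration_fit` with elements `params`
#'   ([respiration_params()]), the underlying `nls` fit, and tibbles from
#'   [tidy()] / [glance()].
#' @export
estimate_respiration <- function(night) {
  if (!all(c("t_air", "rc") %in% names(night))) {
    abort("estimate_respiration: need columns t_air and rc")
  }
  night <- night[complete.cases(night[, c("t_air", "rc")]), ]
  if (nrow(night) < 3) abort("estimate_respiration: need at least 3 night records")
  if (diff(range(night$t_air)) <= 0) {
    abort("estimate_respiration: zero temperature spread, ERc unidentifiable")
  }
  start <- list(rc25 = max(mean(night$rc), 0.1), erc = 10000)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rc ~ rc25 * exp(erc * (t_air - 25) / (298 * 8.314 * (t_air + 273))),
      data = night, start = start,
      lower = c(rc25 = 1e-6, erc = -5e5), upper = c(rc25 = 1e3, erc = 5e5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(paste0("estimate_respiration: fit did not converge (",
                   conditionMessage(e), ")"))
    })
  est <- coef(fit)
  structure(list(params = respiration_params(est[["rc25"]], est[["erc"]]),
                 fit = fit, n = nrow(night)),
            class = "respiration_fit")
}

#' Instantaneous fluxes from a chamber series
#'
#' Applies the transpiration and net-photosynthesis mass balances to every
#' (QC-kept) record, partitions respiration into the two measurement
#' regimes -- at night (`par < night_par`) respiration is read directly
#' from the CO2 balance, during the day it follows the fitted temperature
#' response at chamber air temperature (`t_in + t_dif`) -- and forms gross
#' photosynthesis `Ac,gross = Ac,net + Rc` (with `Ac,gross = 0` at night,
#' where net exchange is respiration itself).
#'
#' @param series A `chamber_series` (ideally QC-filtered and
#'   baseline-corrected).
#' @param cfg A [system_config()].
#' @param resp A [respiration_params()] or `respiration_fit` for daytime
#'   respiration; if `NULL`, it is fitted from this series' own night
#'   records.
#' @param night_par PAR threshold below which a record counts as night,
#'   umol m^-2 s^-1.
#' @return A `flux_series` tibble: `time`, `chamber_id`, `ec`, `ac_net`,
#'   `rc`, `ac_gross`, `night`, `qc_keep`.
#' @export
compute_fluxes <- function(series, cfg = system_config(), resp = NULL,
                           night_par = 5) {
  if (!"qc_keep" %in% names(series)) series$qc_keep <- TRUE
  kept <- series[series$qc_keep, ]
  ec <- compute_ec(kept$vp_in, kept$vp_dif, cfg)
  ac_net <- compute_ac_net(kept$co2_in, kept$co2_dif, ec, cfg)
  night <- kept$radiation < night_par

  if (is.null(resp)) {
    nt <- tibble(t_air = kept$t_in + kept$t_dif, rc = -ac_net)[night, ]
    resp <- estimate_respiration(nt)
  }
  p <- if (inherits(resp, "respiration_fit")) resp$params else resp
  stopifnot(inherits(p, "respiration_params"))

  rc <- respiration_at(kept$t_in + kept$t_dif, p)
  rc[night] <- pmax(-ac_net[night], 0)
  ac_gross <- ifelse(night, 0, ac_net + rc)
  out <- tibble(time = kept$time, chamber_id = kept$chamber_id,
                ec = ec, ac_net = ac_net, rc = rc, ac_gross = ac_gross,
                night = night, qc_keep = TRUE)
  class(out) <- c("flux_series", class(out))
  attr(out, "respiration") <- p
  out
}

#' Daily integrals of canopy fluxes
#'
#' Trapezoidal integration of instantaneous fluxes over the day with unit
#' conversion (mmol s^-1 -> mol d^-1 for water, umol s^-1 -> mol d^-1 for
#' CO2). Gaps longer than `max_gap` cadence steps are not bridged; the
#' affected day is flagged through its `coverage` fraction.
#'
#' @param flux A `flux_series` for a single day per chamber.
#' @param policy A [qc_policy()] (supplies `max_gap` and `min_coverage`).
#' @param cadence_s Nominal record cadence, seconds.
#' @return A `daily_flux` tibble per chamber: `ec_daily` (mol H2O m^-2
#'   d^-1), `ac_gross_daily`, `rc_daily` (mol CO2 m^-2 d^-1), `coverage`,
#'   `reliable`.
#' @export
daily_integrate <- function(flux, policy = qc_policy(), cadence_s = 720) {
  stopifnot(inherits(policy, "qc_policy"))
  flux |>
    group_by(.data$chamber_id) |>
    summarise(
      ec_daily = trapz_day(.data$time, .data$ec, cadence_s, policy$max_gap) / 1000,
      ac_gross_daily = trapz_day(.data$time, .data$ac_gross, cadence_s,
                                 policy$max_gap) / 1e6,
      rc_daily = trapz_day(.data$time, .data$rc, cadence_s, policy$max_gap) / 1e6,
      coverage = day_coverage(.data$time, cadence_s, policy$max_gap),
      .groups = "drop") |>
    mutate(reliable = .data$coverage >= policy$min_coverage) |>
    structure(class = c("daily_flux", class(tibble())))
}

# trapezoid over one day; segments spanning more than max_gap cadence
# steps contribute nothing (the gap is not bridged)
trapz_day <- function(time, x, cadence_s, max_gap) {
  o <- order(time)
  time <- time[o]; x <- x[o]
  if (length(time) < 2) return(0)
  dt <- diff(time)
  w <- ifelse(dt <= max_gap * cadence_s, dt, 0)
  sum(w * (x[-1] + x[-length(x)]) / 2)
}

day_coverage <- function(time, cadence_s, max_gap) {
  time <- sort(time)
  if (length(time) < 2) return(0)
  dt <- diff(time)
  covered <- sum(dt[dt <= max_gap * cadence_s])
  min(1, (covered + cadence_s) / 86400)
}
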