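# Two-fraction (sunlit/shaded) canopy photosynthesis-transpiration model:
# radiation partitioning with scattering, exponential nitrogen profile
# shared between the fractions, FvCB biochemistry with a coupled stomatal
# conductance, Penman-Monteith transpiration, and stomatal down-regulation
# when available water falls short of potential transpiration.

#' Partition canopy leaf area, absorbed PAR and nitrogen into sunlit and
#' shaded fractions
#'
#' Radiation partitioning follows the classical sun/shade scheme: the
#' sunlit leaf area is `(1 - exp(-kb LAI))/kb` with `kb` the direct-beam
#' extinction coefficient from leaf inclination and solar elevation;
#' absorbed PAR per fraction accounts for leaf scattering and canopy
#' reflection, with the shaded fraction receiving diffuse plus scattered
#' beam light. Canopy nitrogen is allocated to the fractions by
#' integrating the exponential SLN profile weighted by the sunlit
#' probability `exp(-kb l)`, so the allocated amounts sum exactly to total
#' canopy N.
#'
#' @param canopy A [canopy_state()].
#' @param elevation Solar elevation, degrees.
#' @param par_dir,par_dif Direct-beam and diffuse incident PAR,
#'   umol m^-2 s^-1.
#' @param params A [leaf_params()] (supplies absorptance and leaf angle).
#' @return A tibble with one row per fraction (`sunlit`, `shaded`):
#'   `lai` (m^2 m^-2), `i_abs` (absorbed PAR, umol m^-2 ground s^-1),
#'   `n_tot` and `n_photo` (total and above-base leaf N, g N m^-2 ground).
#' @export
partition_sunlit_shaded <- function(canopy, elevation, par_dir, par_dif,
                                    params = leaf_params()) {
  stopifnot(inherits(canopy, "canopy_state"))
  L <- canopy$lai
  if (L <= 0) {
    return(tibble(fraction = c("sunlit", "shaded"), lai = 0, i_abs = 0,
                  n_tot = 0, n_photo = 0))
  }
  if (elevation <= 0 && par_dir > 1e-9) {
    abort("partition_sunlit_shaded: direct beam requires elevation > 0")
  }
  sigma <- 1 - params$absorptance
  kd_eff <- canopy$kl_dif                  # effective (with scattering)
  sunup <- elevation > 0 && par_dir > 1e-9

  if (sunup) {
    kb <- kbeam(elevation, params$leaf_angle)
    kb_eff <- kb * sqrt(1 - sigma)
    rho_h <- (1 - sqrt(1 - sigma)) / (1 + sqrt(1 - sigma))
    rho_cb <- 1 - exp(-2 * rho_h * kb / (1 + kb))
    rho_cd <- 1 - exp(-2 * rho_h * kd_eff / (1 + kd_eff))
    lai_sun <- (1 - exp(-kb * L)) / kb
  } else {
    kb <- Inf
    rho_h <- (1 - sqrt(1 - sigma)) / (1 + sqrt(1 - sigma))
    rho_cd <- 1 - exp(-2 * rho_h * kd_eff / (1 + kd_eff))
    lai_sun <- 0
  }
  lai_sh <- L - lai_sun

  i_dif_tot <- (1 - rho_cd) * par_dif * (1 - exp(-kd_eff * L))
  if (sunup) {
    i_beam_tot <- (1 - rho_cb) * par_dir * (1 - exp(-kb_eff * L))
    i_sun_direct <- par_dir * (1 - sigma) * (1 - exp(-kb * L))
    i_sun_dif <- par_dif * (1 - rho_cd) *
      (1 - exp(-(kd_eff + kb) * L)) * kd_eff / (kd_eff + kb)
    i_sun_scat <- par_dir * (
      (1 - rho_cb) * (1 - exp(-(kb_eff + kb) * L)) * kb_eff / (kb_eff + kb) -
        (1 - sigma) * (1 - exp(-2 * kb * L)) / 2)
    i_sun <- i_sun_direct + i_sun_dif + max(i_sun_scat, 0)
    i_tot <- i_beam_tot + i_dif_tot
    i_sun <- min(i_sun, i_tot)
  } else {
    i_tot <- i_dif_tot
    i_sun <- 0
  }
  i_sh <- max(i_tot - i_sun, 0)

  kn <- canopy$kn
  n_tot <- canopy$nc
  if (sunup) {
    n_sun <- canopy$sln0 * (1 - exp(-(kn + kb) * L)) / (kn + kb)
  } else {
    n_sun <- 0
  }
  n_sh <- n_tot - n_sun
  base <- params$sln_base
  np_sun <- max(n_sun - base * lai_sun, 0)
  np_sh <- max(n_sh - base * lai_sh, 0)

  tibble(fraction = c("sunlit", "shaded"),
         lai = c(lai_sun, lai_sh),
         i_abs = c(i_sun, i_sh),
         n_tot = c(n_sun, n_sh),
         n_photo = c(np_sun, np_sh))
}

# non-rectangular hyperbola electron transport
electron_transport <- function(i2, jmax, theta) {
  if (jmax <= 0) return(0)
  b <- i2 + jmax
  (b - sqrt(pmax(b^2 - 4 * theta * i2 * jmax, 0))) / (2 * theta)
}

# FvCB net assimilation at given Ci (extensive, per ground area of the
# fraction): vcmax, j, rd in umol m^-2 s^-1; ci, gamma_star, km in
# umol mol^-1
fvcb_net <- function(ci, vcmax, j, rd, gamma_star, km) {
  wc <- vcmax * (ci - gamma_star) / (ci + km)
  wj <- (j / 4) * (ci - gamma_star) / (ci + 2 * gamma_star)
  pmin(wc, wj) - rd
}

# biochemical parameters at leaf temperature
biochem_at <- function(t_leaf, vcmax25, jmax25, rd25, params) {
  list(
    vcmax = vcmax25 * arrhenius(t_leaf, params$e_vcmax),
    jmax = jmax25 * arrhenius(t_leaf, params$e_jmax),
    rd = rd25 * arrhenius(t_leaf, params$e_rd),
    gamma_star = params$gamma_star25 * arrhenius(t_leaf, params$e_gamma),
    km = params$kc25 * arrhenius(t_leaf, params$e_kc) *
      (1 + params$o2 / (params$ko25 * arrhenius(t_leaf, params$e_ko)))
  )
}

# Solve the coupled stomatal conductance / CO2 diffusion / FvCB system
# for one canopy fraction by root finding on Ci. Returns net assimilation
# (umol m^-2 ground s^-1), stomatal conductance to CO2 (mol m^-2 s^-1)
# and Ci. gs model: gsc = g0*LAI + a1*max(A,0)/((Ca - gamma*)(1 + D/d0)).
solve_coupled <- function(i_abs, lai_f, bio, ca, vpd, params) {
  g0L <- params$g0 * max(lai_f, 1e-9)
  i2 <- i_abs * params$alpha_e
  j <- electron_transport(i2, bio$jmax, params$theta_j)
  gs_of_a <- function(a) {
    g0L + params$a1 * pmax(a, 0) /
      ((ca - bio$gamma_star) * (1 + vpd / params$d0))
  }
  fun <- function(ci) {
    a <- fvcb_net(ci, bio$vcmax, j, bio$rd, bio$gamma_star, bio$km)
    gs_of_a(a) * (ca - ci) - a
  }
  lo <- bio$gamma_star * 0.2 + 1e-3
  hi <- max(3 * ca, 3000)
  root <- tryCatch(uniroot(fun, c(lo, hi), tol = 1e-9)$root,
                   error = function(e) NA_real_)
  if (is.na(root)) {
    # fall back to a coarse scan (degenerate parameter corners)
    grid <- seq(lo, hi, length.out = 2000)
    root <- grid[which.min(abs(vapply(grid, fun, numeric(1))))]
  }
  a <- fvcb_net(root, bio$vcmax, j, bio$rd, bio$gamma_star, bio$km)
  list(a_net = a, gsc = gs_of_a(a), ci = root, j = j)
}

#' Actual stomatal resistance under limited water supply
#'
#' When the water available for transpiration `Ea` falls short of the
#' Penman-Monteith potential `Ep`, stomata must close until transpiration
#' matches supply. Inverting the Penman-Monteith equation for the
#' resistance that delivers exactly `Ea` gives
#' `rsw_a = (Ep - Ea)(s rbh + gamma rbw) / (gamma Ea) + rsw_p Ep / Ea`,
#' which reduces to the unstressed resistance `rsw_p` when `Ea = Ep` and
#' grows without bound as `Ea -> 0`.
#'
#' @param ep Potential transpiration, mmol m^-2 s^-1 (> 0).
#' @param ea Actual available water for transpiration, mmol m^-2 s^-1,
#'   in (0, ep].
#' @param s Slope of the saturation vapour-pressure curve, kPa degC^-1.
#' @param rbh,rbw Boundary-layer resistances to heat and water, s m^-1.
#' @param rsw_p Unstressed stomatal resistance to water, s m^-1.
#' @return Actual stomatal resistance, s m^-1 (>= `rsw_p`).
#' @examples
#' actual_stomatal_resistance(2, 1, s = 0.145, rbh = 25, rbw = 28,
#'                            rsw_p = 100)
#' @export
actual_stomatal_resistance <- function(ep, ea, s, rbh, rbw, rsw_p) {
  if (any(ea <= 0)) abort("actual_stomatal_resistance: Ea must be > 0")
  if (any(ep <= 0)) abort("actual_stomatal_resistance: Ep must be > 0")
  if (any(ea > ep * (1 + 1e-12))) {
    abort("actual_stomatal_resistance: Ea must not exceed Ep")
  }
  gamma <- cf_constants$gamma
  (ep - ea) * (s * rbh + gamma * rbw) / (gamma * ea) + rsw_p * ep / ea
}

# One fraction, one time step, potential mode: coupled assimilation +
# Penman-Monteith with optional leaf energy balance.
leaf_fraction_step <- function(i_abs, lai_f, n_photo, t_air, ca, vp, wind,
                               p_atm, params, rn_par_mult = 1.1,
                               leaf_temp = c("energy_balance", "air"),
                               tol = 0.01, max_iter = 25) {
  leaf_temp <- match.arg(leaf_temp)
  vcmax25 <- params$chi_vcmax * n_photo
  jmax25 <- params$rjv * vcmax25
  rd25 <- params$rd_frac * vcmax25

  rbh_leaf <- 1 / (0.01 * sqrt(max(wind, 0.1) / params$leaf_width))
  rbh <- rbh_leaf / max(lai_f, 1e-9)
  rbw <- rbh / 0.93
  rn <- i_abs * cf_constants$par_w_per_umol * rn_par_mult
  rho_cp <- cf_constants$rho_cp
  gamma <- cf_constants$gamma

  t_leaf <- t_air
  for (it in seq_len(max_iter)) {
    vpd <- max(svp(t_leaf) - vp, 0.01)
    s <- svp_slope(t_leaf)
    bio <- biochem_at(t_leaf, vcmax25, jmax25, rd25, params)
    sol <- solve_coupled(i_abs, lai_f, bio, ca, vpd, params)
    rho_m <- air_molar_density(t_leaf, p_atm)
    rsw_p <- rho_m / (1.6 * max(sol$gsc, 1e-9))
    le <- (s * rn + rho_cp * vpd / rbh) / (s + gamma * (rbw + rsw_p) / rbh)
    le <- max(le, 0)
    if (leaf_temp == "air") break
    t_new <- t_air + (rn - le) * rbh / rho_cp
    t_new <- min(max(t_new, t_air - 10), t_air + 10)
    if (abs(t_new - t_leaf) < tol) { t_leaf <- t_new; break }
    t_leaf <- 0.5 * t_leaf + 0.5 * t_new
  }
  vpd <- max(svp(t_leaf) - vp, 0.01)
  s <- svp_slope(t_leaf)
  ep <- 1000 * le / cf_constants$lambda_mol
  list(a_net = sol$a_net, a_gross = max(sol$a_net + bio$rd, 0),
       gsc = sol$gsc, ci = sol$ci, ep = ep, rsw_p = rsw_p,
       rbh = rbh, rbw = rbw, s = s, t_leaf = t_leaf, bio = bio,
       j = sol$j)
}

# actual (water-limited) assimilation for one fraction given rsw_a
fraction_actual_assim <- function(state, rsw_a, ca, t_leaf, p_atm) {
  rho_m <- air_molar_density(t_leaf, p_atm)
  gsc <- rho_m / (1.6 * rsw_a)
  bio <- state$bio
  solve_lim <- function(v, k) {
    if (v <= 0) return(-bio$rd)
    ainv <- 1 / gsc
    b <- ca + k + ainv * (v - bio$rd)
    cc <- v * (ca - bio$gamma_star) - bio$rd * (ca + k)
    (b - sqrt(pmax(b^2 - 4 * ainv * cc, 0))) / (2 * ainv)
  }
  ac <- solve_lim(bio$vcmax, bio$km)
  aj <- solve_lim(state$j / 4, 2 * bio$gamma_star)
  a_net <- min(ac, aj)
  list(a_net = a_net, a_gross = max(a_net + bio$rd, 0))
}

#' Canopy gas exchange over a weather series
#'
#' Runs the sun/shade canopy model for every record of a weather series.
#' In potential mode (no water input) it returns potential canopy
#' transpiration `ec_pot` and gross photosynthesis `ac_gross_pot` as the
#' sums of the two fractions. When an available-water input is supplied
#' (`water`, a per-record transpiration allowance, or `water_fraction`, a
#' fixed fraction of potential), the allowance is partitioned between the
#' fractions in proportion to their potential transpiration, the actual
#' stomatal resistance follows from [actual_stomatal_resistance()], and
#' actual photosynthesis is recomputed with stomata so constrained. Supply
#' in excess of potential does not stimulate fluxes beyond potential.
#'
#' @param canopy A [canopy_state()].
#' @param weather A `weather_series` (or data frame with `time`, `par`,
#'   `t_air`, `co2`, `vp`, `wind`, `p_atm`).
#' @param params A [leaf_params()].
#' @param water Optional numeric: total canopy transpiration allowance per
#'   record, mmol H2O m^-2 s^-1 (scalar or one value per record).
#' @param water_fraction Optional scalar in (0, 1]: allowance as a
#'   fraction of each record's potential transpiration.
#' @param latitude,day_of_year Solar-geometry inputs; defaults come from
#'   the attributes [generate_weather()] leaves on the series.
#' @param rn_par_mult Net radiation per unit absorbed PAR (W per W);
#'   2 treats absorbed PAR as half of absorbed shortwave, with longwave
#'   exchange neglected.
#' @param leaf_temp `"energy_balance"` (fixed-point iteration, default) or
#'   `"air"`.
#' @param detail Return per-fraction columns?
#' @return A `canopy_run` tibble: `time`, `elevation`, `ec_pot`,
#'   `ac_gross_pot` (potential), `ec`, `ac_gross` (actual; equal to
#'   potential when water is not limiting), and per-fraction detail when
#'   requested.
#' @export
canopy_gas_exchange <- function(canopy, weather, params = leaf_params(),
                                water = NULL, water_fraction = NULL,
                                latitude = NULL, day_of_year = NULL,
                                rn_par_mult = 1.1,
                                leaf_temp = c("energy_balance", "air"),
                                detail = FALSE) {
  stopifnot(inherits(canopy, "canopy_state"))
  leaf_temp <- match.arg(leaf_temp)
  latitude <- latitude %||% attr(weather, "latitude")
  day_of_year <- day_of_year %||% attr(weather, "day_of_year")
  if (is.null(latitude) || is.null(day_of_year)) {
    abort("canopy_gas_exchange: latitude and day_of_year are required")
  }
  if (!is.null(water) && !is.null(water_fraction)) {
    abort("canopy_gas_exchange: give water or water_fraction, not both")
  }
  if (!is.null(water_fraction)) {
    stopifnot(water_fraction > 0, water_fraction <= 1)
  }
  n <- nrow(weather)
  if (!is.null(water)) {
    if (length(water) == 1) water <- rep(water, n)
    if (length(water) != n) {
      abort("canopy_gas_exchange: water must be scalar or one value per record")
    }
  }
  sol <- solar_position(weather$time, latitude, day_of_year,
                        par = weather$par)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- weather[i, ]
    fr <- partition_sunlit_shaded(canopy, sol$elevation[i], sol$par_dir[i],
                                  sol$par_dif[i], params)
    if (canopy$lai <= 0) {
      rows[[i]] <- tibble(ec_pot = 0, ac_gross_pot = 0, ec = 0, ac_gross = 0,
                          ep_sun = 0, ep_sh = 0, ap_sun = 0, ap_sh = 0,
                          t_leaf_sun = w$t_air, t_leaf_sh = w$t_air)
      next
    }
    states <- lapply(seq_len(2), function(k) {
      if (fr$lai[k] <= 1e-9) return(NULL)
      leaf_fraction_step(fr$i_abs[k], fr$lai[k], fr$n_photo[k], w$t_air,
                         w$co2, w$vp, w$wind, w$p_atm, params,
                         rn_par_mult = rn_par_mult, leaf_temp = leaf_temp)
    })
    ep <- vapply(states, function(s) if (is.null(s)) 0 else s$ep, numeric(1))
    ap <- vapply(states, function(s) if (is.null(s)) 0 else s$a_gross,
                 numeric(1))
    ec_pot <- sum(ep)
    ac_pot <- sum(ap)

    allowance <- if (!is.null(water)) water[i]
                 else if (!is.null(water_fraction)) water_fraction * ec_pot
                 else NA_real_
    if (is.na(allowance) || allowance >= ec_pot || ec_pot <= 1e-9) {
      ec <- ec_pot; ac <- ac_pot
    } else {
      ea <- allowance * ep / ec_pot
      aa <- ap
      for (k in seq_len(2)) {
        st <- states[[k]]
        if (is.null(st) || ep[k] <= 1e-9 || ea[k] <= 0) { aa[k] <- 0; next }
        rsw_a <- actual_stomatal_resistance(ep[k], ea[k], st$s, st$rbh,
                                            st$rbw, st$rsw_p)
        aa[k] <- fraction_actual_assim(st, rsw_a, w$co2, st$t_leaf,
                                       w$p_atm)$a_gross
      }
      ec <- allowance
      ac <- sum(aa)
    }
    rows[[i]] <- tibble(
      ec_pot = ec_pot, ac_gross_pot = ac_pot, ec = ec, ac_gross = ac,
      ep_sun = ep[1], ep_sh = ep[2], ap_sun = ap[1], ap_sh = ap[2],
      t_leaf_sun = if (is.null(states[[1]])) w$t_air else states[[1]]$t_leaf,
      t_leaf_sh = if (is.null(states[[2]])) w$t_air else states[[2]]$t_leaf)
  }
  out <- bind_cols(tibble(time = weather$time, elevation = sol$elevation),
                   bind_rows(rows))
  if (!detail) {
    out <- out |> select("time", "elevation", "ec_pot", "ac_gross_pot",
                         "ec", "ac_gross")
  }
  class(out) <- c("canopy_run", class(out))
  out
}
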