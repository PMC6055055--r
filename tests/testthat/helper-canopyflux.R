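# Shared fixtures and oracles, all built in code.

# canopy from a printed (LAI, mean SLN) pair: invert the profile integral
# for SLN0 so that mean SLN and total N match the table values
canopy_from_mean <- function(lai, sln_mean, kn) {
  sln0 <- sln_mean * kn * lai / (1 - exp(-kn * lai))
  canopy_state(lai, sln0, kn = kn)
}

# the measured treatment canopies (LAI and mean SLN as printed; kn from
# the size-dependent decline, larger canopies flatter)
treatment_canopies <- function() {
  list(
    N1 = canopy_from_mean(1.84, 0.84, 0.45),
    N2 = canopy_from_mean(2.26, 0.94, 0.42),
    N3 = canopy_from_mean(2.59, 1.02, 0.40),
    WW1 = canopy_from_mean(2.01, 0.97, 0.45),
    WW2 = canopy_from_mean(1.97, 0.68, 0.48),
    WS2 = canopy_from_mean(1.26, 1.03, 0.60)
  )
}

# default one-day weather at 12-min cadence (deterministic)
fixture_weather <- function(...) generate_weather(seed = 42, ...)

# noiseless chamber ground truth for a canopy under this weather
fixture_truth <- function(weather, canopy = canopy_state(2.3, 1.2, kn = 0.4),
                          params = leaf_params(),
                          resp = respiration_params(4, 9559),
                          water_fraction = NULL) {
  run <- canopy_gas_exchange(canopy, weather, params,
                             water_fraction = water_fraction)
  rc <- respiration_at(weather$t_air, resp)
  night <- weather$par < 5
  tibble::tibble(time = weather$time, ec = run$ec,
                 ac_net = ifelse(night, -rc, run$ac_gross - rc))
}

# Multilayer oracle: integrate the package's own leaf model over n_layers
# thin layers instead of two big leaves. Same biochemistry and coupling,
# independent canopy integration scheme.
multilayer_canopy <- function(canopy, elevation, par_dir, par_dif, t_air,
                              co2, vp, wind, p_atm, params,
                              n_layers = 200) {
  L <- canopy$lai
  dl <- L / n_layers
  l_mid <- (seq_len(n_layers) - 0.5) * dl
  sigma <- 1 - params$absorptance
  kd_eff <- canopy$kl_dif
  sunup <- elevation > 0 && par_dir > 1e-9
  rho_h <- (1 - sqrt(1 - sigma)) / (1 + sqrt(1 - sigma))
  rho_cd <- 1 - exp(-2 * rho_h * kd_eff / (1 + kd_eff))
  if (sunup) {
    kb <- canopyflux:::kbeam(elevation, params$leaf_angle)
    kb_eff <- kb * sqrt(1 - sigma)
    rho_cb <- 1 - exp(-2 * rho_h * kb / (1 + kb))
    f_sun <- exp(-kb * l_mid)
  } else {
    kb <- Inf
    f_sun <- rep(0, n_layers)
  }
  # absorbed flux density profiles (per unit leaf area at depth l):
  # derivative of the canopy absorption integrals used by the big-leaf
  # scheme
  i_dif <- (1 - rho_cd) * par_dif * kd_eff * exp(-kd_eff * l_mid)
  if (sunup) {
    i_beam_tot <- (1 - rho_cb) * par_dir * kb_eff * exp(-kb_eff * l_mid)
    i_dir_sunlit <- par_dir * (1 - sigma) * kb          # per sunlit leaf
    i_scat <- i_beam_tot - par_dir * (1 - sigma) * kb * exp(-kb * l_mid)
    i_scat <- pmax(i_scat, 0)
  } else {
    i_dir_sunlit <- 0
    i_scat <- rep(0, n_layers)
  }
  sln <- canopy$sln0 * exp(-canopy$kn * l_mid)
  np <- pmax(sln - params$sln_base, 0)

  run_leaf <- function(i_abs_leaf, np_leaf, lai_w) {
    # one thin layer as a tiny "fraction" of leaf area lai_w
    st <- canopyflux:::leaf_fraction_step(
      i_abs_leaf * lai_w, lai_w, np_leaf * lai_w, t_air, co2, vp, wind,
      p_atm, params, leaf_temp = "air")
    c(ap = st$a_gross, ep = st$ep)
  }
  tot <- c(ap = 0, ep = 0)
  for (k in seq_len(n_layers)) {
    i_sh_leaf <- i_dif[k] + i_scat[k]
    w_sun <- f_sun[k] * dl
    w_sh <- (1 - f_sun[k]) * dl
    if (w_sun > 1e-12) {
      tot <- tot + run_leaf(i_sh_leaf + i_dir_sunlit, np[k], w_sun)
    }
    if (w_sh > 1e-12) {
      tot <- tot + run_leaf(i_sh_leaf, np[k], w_sh)
    }
  }
  tot
}
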