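# Parameter containers. These are plain validated lists with a class
# attribute so they print compactly and fail fast on nonsense values.

#' Leaf-level photosynthesis and exchange parameters
#'
#' Parameters of the coupled FvCB biochemistry / stomatal conductance /
#' Penman-Monteith leaf model used by [canopy_gas_exchange()]. Values are a
#' configuration input: the defaults describe a generic high-capacity C3
#' annual (nitrogen-rich, thin-leaved) and are meant to be replaced with
#' crop-specific estimates where available.
#'
#' @param chi_vcmax Slope of Vcmax25 against specific leaf nitrogen,
#'   umol CO2 (g N)^-1 s^-1.
#' @param sln_base Base (non-photosynthetic) specific leaf nitrogen below
#'   which Vcmax is zero, g N m^-2 leaf.
#' @param rjv Ratio of Jmax25 to Vcmax25, dimensionless.
#' @param alpha_e Quantum yield of electron transport on an absorbed-PAR
#'   basis, mol e- (mol photons)^-1.
#' @param theta_j Curvature of the non-rectangular hyperbola light response.
#' @param rd_frac Dark respiration at 25 degC as a fraction of Vcmax25.
#' @param g0 Residual stomatal conductance to CO2, mol m^-2 s^-1 (per unit
#'   leaf area); keeps the Penman-Monteith equation defined in the dark.
#' @param a1 Slope of the stomatal conductance response to net assimilation.
#' @param d0 Vapour-pressure-deficit sensitivity of stomata, kPa.
#' @param e_vcmax,e_jmax,e_kc,e_ko,e_gamma,e_rd Activation energies,
#'   J mol^-1.
#' @param kc25 Michaelis constant of Rubisco for CO2 at 25 degC, umol mol^-1.
#' @param ko25 Michaelis constant for O2 at 25 degC, mmol mol^-1.
#' @param gamma_star25 CO2 compensation point without Rd at 25 degC,
#'   umol mol^-1.
#' @param o2 Oxygen mole fraction, mmol mol^-1.
#' @param absorptance Leaf PAR absorptance (1 - scattering coefficient).
#' @param leaf_width Characteristic leaf width for the boundary layer, m.
#' @param leaf_angle Leaf inclination from horizontal used for the
#'   direct-beam extinction coefficient, degrees.
#' @return An object of class `leaf_params` (a named list).
#' @examples
#' p <- leaf_params()
#' p$chi_vcmax
#' @export
leaf_params <- function(chi_vcmax = 120,
                        sln_base = 0.2,
                        rjv = 1.9,
                        alpha_e = 0.425,
                        theta_j = 0.7,
                        rd_frac = 0.015,
                        g0 = 0.01,
                        a1 = 2,
                        d0 = 10,
                        e_vcmax = 65330,
                        e_jmax = 43540,
                        e_kc = 79430,
                        e_ko = 36380,
                        e_gamma = 37830,
                        e_rd = 46390,
                        kc25 = 404.9,
                        ko25 = 278.4,
                        gamma_star25 = 42.75,
                        o2 = 210,
                        absorptance = 0.85,
                        leaf_width = 0.08,
                        leaf_angle = 15) {
  p <- list(
    chi_vcmax = chi_vcmax, sln_base = sln_base, rjv = rjv,
    alpha_e = alpha_e, theta_j = theta_j, rd_frac = rd_frac,
    g0 = g0, a1 = a1, d0 = d0,
    e_vcmax = e_vcmax, e_jmax = e_jmax, e_kc = e_kc, e_ko = e_ko,
    e_gamma = e_gamma, e_rd = e_rd,
    kc25 = kc25, ko25 = ko25, gamma_star25 = gamma_star25, o2 = o2,
    absorptance = absorptance, leaf_width = leaf_width,
    leaf_angle = leaf_angle
  )
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    abort(paste0("leaf_params: non-positive or non-scalar value for: ",
                 paste(bad, collapse = ", ")))
  }
  if (theta_j >= 1 || alpha_e >= 1 || absorptance > 1 || rd_frac > 0.2) {
    abort("leaf_params: ratio parameter outside its physiological range")
  }
  structure(p, class = "leaf_params")
}

#' Chamber system configuration
#'
#' Geometry and flow settings of a flow-through canopy chamber. The molar
#' air flux `u_e` may be given directly or derived from a volumetric flow
#' via the ideal gas law (see `flow_temperature`).
#'
#' @param u_e Molar air flux entering the chamber, mol s^-1. If `NULL`, it
#'   is computed from `flow_m3_s`.
#' @param flow_m3_s Volumetric air flux, m^3 s^-1.
#' @param flow_temperature Temperature at which the volumetric flow is
#'   converted to molar units, degC. Either a number or `"chamber"` to use
#'   each record's chamber air temperature.
#' @param a Chamber ground (cross-section) area, m^2.
#' @param p Chamber air pressure, kPa; standard pressure is used as a proxy
#'   since chamber overpressure is a few Pa at most.
#' @param volume Chamber volume, m^3 (used only for residence-time
#'   diagnostics).
#' @param trans_side,trans_top Light transmittance of the side wall and top
#'   disc, dimensionless in (0, 1].
#' @return An object of class `system_config`.
#' @examples
#' cfg <- system_config()
#' chamber_residence_time(cfg) # ~70 s
#' @export
system_config <- function(u_e = NULL,
                          flow_m3_s = 4.3e-3,
                          flow_temperature = 25,
                          a = 0.2,
                          p = cf_constants$P_std,
                          volume = 0.3,
                          trans_side = 0.87,
                          trans_top = 0.93) {
  if (is.null(u_e)) {
    t_conv <- if (identical(flow_temperature, "chamber")) 25 else flow_temperature
    u_e <- molar_flow(flow_m3_s, t_air = t_conv, p = p)
  }
  stopifnot(u_e > 0, a > 0, p > 0, volume > 0,
            trans_side > 0, trans_side <= 1, trans_top > 0, trans_top <= 1)
  structure(list(u_e = u_e, flow_m3_s = flow_m3_s,
                 flow_temperature = flow_temperature, a = a, p = p,
                 volume = volume, trans_side = trans_side,
                 trans_top = trans_top),
            class = "system_config")
}

#' @rdname system_config
#' @param cfg A `system_config`.
#' @return `chamber_residence_time()` returns the time for one complete
#'   volume air change, seconds.
#' @export
chamber_residence_time <- function(cfg) {
  stopifnot(inherits(cfg, "system_config"))
  cfg$volume / cfg$flow_m3_s
}

#' Canopy physiological state
#'
#' The canopy description consumed by the sun/shade model: leaf area index,
#' the top-of-canopy specific leaf nitrogen with its extinction coefficient,
#' and the diffuse-light extinction coefficient. Total canopy leaf nitrogen
#' `nc` is derived from the profile integral
#' `Nc = SLN0 (1 - exp(-kn LAI)) / kn` (or `SLN0 * LAI` as kn -> 0).
#'
#' @param lai Leaf area index, m^2 leaf m^-2 ground.
#' @param sln0 Specific leaf nitrogen at the top of the canopy, g N m^-2 leaf.
#' @param kn Nitrogen extinction coefficient, m^2 m^-2 (>= 0; 0 = uniform).
#' @param kl_dif Diffuse-light extinction coefficient, m^2 m^-2.
#' @param leaf_angle Leaf inclination, degrees.
#' @return An object of class `canopy_state` with derived fields `nc`
#'   (g N m^-2 ground) and `sln_mean`.
#' @examples
#' canopy_state(lai = 2.3, sln0 = 1.2, kn = 0.4)
#' @export
canopy_state <- function(lai, sln0, kn = 0.4, kl_dif = 0.96,
                         leaf_angle = 15) {
  stopifnot(lai >= 0, sln0 > 0, kn >= 0, kl_dif > 0,
            leaf_angle > 0, leaf_angle < 90)
  nc <- cumulative_nitrogen(lai, sln0, kn)
  structure(list(lai = lai, sln0 = sln0, kn = kn, kl_dif = kl_dif,
                 leaf_angle = leaf_angle, nc = nc,
                 sln_mean = if (lai > 0) nc / lai else sln0),
            class = "canopy_state")
}

#' Cumulative canopy nitrogen above a given depth
#'
#' Integral of the exponential specific-leaf-nitrogen profile
#' `SLN(l) = SLN0 exp(-kn l)` from the canopy top to cumulative leaf area
#' `lai`, with the uniform-profile limit handled continuously as kn -> 0.
#'
#' @param lai Cumulative leaf area index from the top, m^2 m^-2.
#' @param sln0 Top-of-canopy specific leaf nitrogen, g N m^-2 leaf.
#' @param kn Nitrogen extinction coefficient, m^2 m^-2.
#' @return Cumulative leaf nitrogen, g N m^-2 ground.
#' @export
cumulative_nitrogen <- function(lai, sln0, kn) {
  stopifnot(all(lai >= 0), sln0 > 0, kn >= 0)
  if (kn < 1e-10) sln0 * lai else sln0 * (1 - exp(-kn * lai)) / kn
}

#' Quality-control policy for chamber records
#'
#' Spike rejection on the entrance CO2 and vapour-pressure signals: a value
#' is flagged when it deviates from a centred rolling median by more than
#' `k` robust standard deviations (1.4826 x MAD of the residuals).
#'
#' @param window Rolling-median window, records (odd; default 7).
#' @param k Rejection threshold in robust SD units.
#' @param floor_co2,floor_vp Absolute residual floors (umol mol^-1, kPa)
#'   below which a deviation is never flagged; they stop the detector from
#'   firing on the curvature of a smooth diurnal course when instrument
#'   noise is negligible.
#' @param min_coverage Minimum fraction of a day with valid records for the
#'   daily integral to be considered reliable.
#' @param max_gap Longest gap, in cadence steps, interpolated across during
#'   daily integration.
#' @return An object of class `qc_policy`.
#' @export
qc_policy <- function(window = 7, k = 4, floor_co2 = 1, floor_vp = 0.02,
                      min_coverage = 0.5, max_gap = 3) {
  stopifnot(window >= 3, window %% 2 == 1, k > 0, floor_co2 >= 0,
            floor_vp >= 0, min_coverage >= 0, min_coverage <= 1,
            max_gap >= 1)
  structure(list(window = window, k = k, floor_co2 = floor_co2,
                 floor_vp = floor_vp, min_coverage = min_coverage,
                 max_gap = max_gap), class = "qc_policy")
}

#' @export
print.leaf_params <- function(x, ...) {
  cat("<leaf_params>\n")
  print(unlist(x))
  invisible(x)
}

#' @export
print.canopy_state <- function(x, ...) {
  cat(sprintf(
    "<canopy_state> LAI %.2f, SLN0 %.2f, kn %.2f, kL(dif) %.2f, Nc %.2f g N m-2\n",
    x$lai, x$sln0, x$kn, x$kl_dif, x$nc))
  invisible(x)
}

#' @export
print.system_config <- function(x, ...) {
  cat(sprintf(
    "<system_config> u_e %.4f mol s-1, a %.2f m2, P %.1f kPa, volume %.2f m3\n",
    x$u_e, x$a, x$p, x$volume))
  invisible(x)
}
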