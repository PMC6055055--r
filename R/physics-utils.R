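# Physical constants and small psychrometric helpers shared across modules.
# Units: pressures kPa, temperatures degC (converted to K where needed),
# molar fluxes mol or mmol m^-2 s^-1, resistances s m^-1.

#' Physical constants used throughout the package
#'
#' @format A named list:
#' \describe{
#'   \item{R_gas}{universal gas constant, 8.314 J K^-1 mol^-1}
#'   \item{gamma}{psychrometric constant, 0.067 kPa degC^-1}
#'   \item{lambda_mol}{latent heat of vaporisation of water, J mol^-1}
#'   \item{rho_cp}{volumetric heat capacity of air, J m^-3 K^-1}
#'   \item{P_std}{standard air pressure, kPa}
#'   \item{par_w_per_umol}{W per umol photons for solar PAR (1/4.56)}
#' }
#' @export
cf_constants <- list(
  R_gas         = 8.314,
  gamma         = 0.067,
  lambda_mol    = 44100,
  rho_cp        = 1200,
  P_std         = 101.3,
  par_w_per_umol = 1 / 4.56
)

#' Saturated vapour pressure and its slope
#'
#' Tetens-type formulation of the saturation vapour pressure of water over a
#' plane surface and its derivative with respect to temperature, the `s` term
#' of the Penman-Monteith equation.
#'
#' @param t_air Air (or leaf) temperature, degC.
#' @return `svp()` returns saturation vapour pressure in kPa;
#'   `svp_slope()` its slope in kPa degC^-1.
#' @examples
#' svp(25)
#' svp_slope(20)
#' @export
svp <- function(t_air) 0.6108 * exp(17.27 * t_air / (t_air + 237.3))

#' @rdname svp
#' @export
svp_slope <- function(t_air) 4098 * svp(t_air) / (t_air + 237.3)^2

#' Convert a volumetric air flow to a molar flow
#'
#' Chamber blowers are regulated on a volumetric basis while the flux
#' equations need a molar flow; the conversion uses the ideal gas law at the
#' stated temperature and pressure.
#'
#' @param flow_m3_s Volumetric flow, m^3 s^-1.
#' @param t_air Temperature at which the flow is converted, degC.
#' @param p Air pressure, kPa.
#' @return Molar flow, mol s^-1.
#' @examples
#' molar_flow(4.3e-3, t_air = 25) # ~0.176 mol s^-1
#' @export
molar_flow <- function(flow_m3_s, t_air = 25, p = cf_constants$P_std) {
  stopifnot(flow_m3_s > 0, p > 0)
  p * 1000 * flow_m3_s / (cf_constants$R_gas * (t_air + 273.15))
}

# molar density of air, mol m^-3
air_molar_density <- function(t_air, p = cf_constants$P_std) {
  p * 1000 / (cf_constants$R_gas * (t_air + 273.15))
}

# simple Arrhenius temperature scaling relative to 25 degC
arrhenius <- function(t_c, e_act) {
  exp(e_act * (t_c - 25) / (298.15 * cf_constants$R_gas * (t_c + 273.15)))
}

`%||%` <- rlang::`%||%`
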