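# Solar geometry: elevation from standard declination / hour-angle
# formulas, and a clearness-based split of PAR into direct and diffuse.

#' Solar position and direct/diffuse split
#'
#' Computes solar elevation from latitude, day of year and local solar time,
#' and partitions incident PAR into direct-beam and diffuse components with
#' an atmospheric-transmission (clearness) relation: the direct fraction is
#' `tau^(1/sin(beta))`, so low sun implies a long optical path and a high
#' diffuse share.
#'
#' @param time Seconds since local midnight (solar time); vectorised.
#' @param latitude Latitude, degrees (positive north), in \[-90, 90\].
#' @param day_of_year Integer day of year, 1-366.
#' @param par Incident PAR to split, umol m^-2 s^-1 (optional).
#' @param tau Clear-sky atmospheric transmittance per unit air mass.
#' @return A tibble with `time`, `elevation` (degrees, negative below the
#'   horizon), `sin_beta`, and when `par` is supplied `par_dir`, `par_dif`.
#' @examples
#' solar_position(12 * 3600, latitude = 45, day_of_year = 172)
#' @export
solar_position <- function(time, latitude, day_of_year, par = NULL,
                           tau = 0.72) {
  if (!is.numeric(latitude) || length(latitude) != 1 ||
      latitude < -90 || latitude > 90) {
    abort("solar_position: latitude must be a single value in [-90, 90]")
  }
  if (!is.numeric(day_of_year) || length(day_of_year) != 1 ||
      day_of_year < 1 || day_of_year > 366) {
    abort("solar_position: day_of_year must be in [1, 366]")
  }
  stopifnot(tau > 0, tau < 1)
  decl <- -23.45 * pi / 180 * cos(2 * pi * (day_of_year + 10) / 365)
  lat <- latitude * pi / 180
  hour_angle <- pi * (time / 3600 - 12) / 12
  sin_beta <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hour_angle)
  elevation <- asin(pmin(1, pmax(-1, sin_beta))) * 180 / pi
  out <- tibble(time = time, elevation = elevation, sin_beta = sin_beta)
  if (!is.null(par)) {
    fdir <- ifelse(sin_beta > 0.01, tau^(1 / pmax(sin_beta, 0.01)), 0)
    out$par_dir <- par * fdir
    out$par_dif <- par * (1 - fdir)
    out$par_dir[out$sin_beta <= 0] <- 0
    out$par_dif[out$sin_beta <= 0] <- 0
  }
  out
}

# Direct-beam extinction coefficient for leaves of fixed inclination
# `leaf_angle` (degrees from horizontal) at solar elevation `beta`
# (degrees): Goudriaan's projection of an inclined leaf onto the
# horizontal, divided by sin(beta).
kbeam <- function(elevation, leaf_angle = 15) {
  beta <- pmax(elevation, 1e-6) * pi / 180
  alpha <- leaf_angle * pi / 180
  sb <- sin(beta)
  proj <- ifelse(
    sb >= sin(alpha),
    sb * cos(alpha),
    (2 / pi) * (sb * cos(alpha) * asin(pmin(1, tan(beta) / tan(alpha))) +
                  sqrt(pmax(0, sin(alpha)^2 - sb^2)))
  )
  proj / sb
}
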