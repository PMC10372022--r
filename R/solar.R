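#' Solar elevation angle (NOAA low-precision algorithm)
#'
#' Geometric elevation of the sun above the horizon, computed from the
#' NOAA low-precision solar-position approximation: a Fourier-series
#' declination and equation of time as functions of the fractional year,
#' combined with the local hour angle.  No atmospheric refraction
#' correction is applied; a 365-day year is assumed.  Accuracy is a few
#' hundredths of a degree in the equation-of-time term and about a tenth
#' of a degree overall — far finer than the day/night threshold needs.
#'
#' Diel vertical migration is keyed to the sign of this angle: migrating
#' krill swim down while the sun is above the horizon and up while it is
#' below.
#'
#' @param lat,lon degrees (vectorized); `lon` east-positive.
#' @param time a `POSIXct` (UTC) or anything `as.POSIXct` accepts
#'   (interpreted as UTC).
#' @return elevation angle(s) in degrees; positive when the sun is up.
#' @examples
#' # polar day: the sun never sets at 70 S in mid-December
#' solar_elevation(-70, -64, as.POSIXct("2008-12-15 04:16:00", tz = "UTC"))
#' @export
solar_elevation <- function(lat, lon, time) {
  stopifnot(all(abs(lat) <= 90))
  time <- as.POSIXct(time, tz = "UTC")
  lt <- as.POSIXlt(time, tz = "UTC")
  doy <- lt$yday + 1
  hour_frac <- lt$hour + lt$min / 60 + lt$sec / 3600
  gamma <- 2 * pi / 365 * (doy - 1 + (hour_frac - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) -
                        0.032077 * sin(gamma) - 0.014615 * cos(2 * gamma) -
                        0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  tst <- hour_frac * 60 + 4 * lon + eqtime
  ha <- (tst / 4 - 180) * pi / 180
  lat_r <- lat * pi / 180
  sin_el <- sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(ha)
  asin(pmin(pmax(sin_el, -1), 1)) * 180 / pi
}

#' Is the sun above the horizon?
#'
#' @inheritParams solar_elevation
#' @return logical vector; `TRUE` while the geometric solar elevation is
#'   positive.
#' @export
sun_above_horizon <- function(lat, lon, time) {
  solar_elevation(lat, lon, time) > 0
}
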