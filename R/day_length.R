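#' Civil daylight duration from latitude and day of year
#'
#' Computes sunrise-to-sunset day length with the standard
#' solar-declination / hour-angle formula: the declination is
#' \eqn{\delta = -23.44^\circ \cos(2\pi (d + 10)/365)} and the half-day
#' hour angle is \eqn{\omega_0 = \arccos(-\tan\phi \tan\delta)}, giving
#' \eqn{L = (24/\pi)\,\omega_0} hours. Twilight and atmospheric refraction
#' are ignored; the calendar is non-leap (365 days).
#'
#' @param latitude Latitude in decimal degrees north. Must satisfy
#'   `abs(latitude) < 66.5`; polar day/night is not handled.
#' @param day_of_year Integer day of the (non-leap) year, 1--366.
#' @return Day length in hours, in (0, 24). Vectorized over both arguments.
#' @examples
#' day_length(35, 172)  # midsummer in central Japan, ~14.5 h
#' @export
day_length <- function(latitude, day_of_year) {
  if (any(abs(latitude) >= 66.5)) {
    stop("day_length() supports |latitude| < 66.5 degrees only")
  }
  if (any(day_of_year < 1 | day_of_year > 366)) {
    stop("day_of_year must be in 1..366")
  }
  decl <- -23.44 * pi / 180 * cos(2 * pi * (day_of_year + 10) / 365)
  cos_h <- pmin(1, pmax(-1, -tan(latitude * pi / 180) * tan(decl)))
  24 / pi * acos(cos_h)
}
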