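# Civil twilight from a standard low-accuracy solar-position approximation
# (fractional-year Fourier expansions for declination and the equation of
# time, then the hour-angle equation for a chosen zenith).

.solarCoefs <- function(date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  g <- 2 * pi / 365 * (doy - 1 + 0.5)  # fractional year at local noon
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
    0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl)
}

# Evening instant (UTC) when the solar zenith reaches `zenith` degrees on
# the given local date.
.solarEvening <- function(lat, lon, date, zenith) {
  s <- .solarCoefs(date)
  phi <- .deg2rad(lat)
  cosha <- cos(.deg2rad(zenith)) / (cos(phi) * cos(s$decl)) -
    tan(phi) * tan(s$decl)
  if (!is.finite(cosha) || abs(cosha) > 1) {
    stop(sprintf(
      "sun does not cross zenith %g deg at lat %g on %s", zenith, lat,
      format(as.Date(date))))
  }
  ha <- .rad2deg(acos(cosha))
  minutesUTC <- 720 - 4 * (lon - ha) - s$eqtime
  as.POSIXct(as.Date(date), tz = "UTC") + minutesUTC * 60
}

#' Evening civil twilight at a site
#'
#' The evening instant when the sun reaches 6 degrees below the horizon
#' (solar zenith 96 degrees) on the given local date -- the nominal
#' departure time of nocturnal migrants. Uses a standard low-accuracy solar
#' approximation (adequate to a few minutes at mid latitudes); an explicit
#' per-date override takes precedence when supplied.
#'
#' @param lat,lon site coordinates, degrees; \code{abs(lat)} must be < 60
#'   (polar twilight edge cases are out of scope)
#' @param date local calendar date of the evening
#' @param override optional POSIXct returned verbatim (e.g., observed
#'   departure times)
#' @return POSIXct instant in UTC
#' @examples
#' civilTwilight(0, 0, as.Date("2020-03-20"))  # ~24 min after 18:00 UTC
#' @export
civilTwilight <- function(lat, lon, date, override = NULL) {
  if (!is.null(override)) return(as.POSIXct(override, tz = "UTC"))
  if (abs(lat) >= 60) stop("civilTwilight supports |lat| < 60 only")
  .solarEvening(lat, lon, date, zenith = 96)
}

#' Evening sunset at a site
#'
#' Standard sunset (solar zenith 90.833 degrees, accounting for refraction
#' and the solar disc) from the same approximation as
#' \code{\link{civilTwilight}}; civil twilight always falls later than
#' sunset for the same site and date.
#'
#' @inheritParams civilTwilight
#' @return POSIXct instant in UTC
#' @export
sunsetUTC <- function(lat, lon, date) {
  if (abs(lat) >= 60) stop("sunsetUTC supports |lat| < 60 only")
  .solarEvening(lat, lon, date, zenith = 90.833)
}
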