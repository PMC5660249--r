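# Flight-range arithmetic downstream of externally supplied endurance
# estimates (flight-biomechanics endurance and airspeed are inputs, not
# modelled here).

#' Flight range under a sustained tailwind
#'
#' Distance covered before energetic stores run out:
#' \code{(airspeed + tailwind) * endurance}, floored at zero when the
#' headwind exceeds the airspeed. Reference endurance inputs for a
#' medium-sized thrush with maximal fuel: 84 h at a constant 10 m/s
#' airspeed, or 68 h under the optimized (faster) airspeed schedule taken
#' at a nominal 13 m/s.
#'
#' @param airspeed airspeed, m/s (> 0)
#' @param tailwind sustained tailwind, m/s (negative = headwind)
#' @param endurance endurance, hours (> 0)
#' @param roundTo optional rounding granularity in km (reported values mix
#'   nearest-10 and nearest-100 rounding); NULL for no rounding
#' @return range in km
#' @examples
#' rangeKm(10, 0, 84, roundTo = 10)      # 3020 km in still air
#' rangeKm(13, -9.2, 68, roundTo = 10)   # 930 km against a 9.2 m/s headwind
#' @export
rangeKm <- function(airspeed, tailwind, endurance, roundTo = NULL) {
  stopifnot(airspeed > 0, endurance > 0)
  groundspeed <- pmax(airspeed + tailwind, 0)
  km <- groundspeed * endurance * 3.6  # m/s * h -> km
  if (!is.null(roundTo)) km <- round(km / roundTo) * roundTo
  km
}

#' Largest sustained headwind permitting a crossing
#'
#' The maximum headwind magnitude under which a flight of
#' \code{distanceKm} is still completed before endurance runs out:
#' \code{airspeed - distanceKm / (endurance * 3.6)}. A negative return
#' value means the distance is unreachable even in still air.
#' \code{rangeKm} at exactly this headwind returns exactly
#' \code{distanceKm} (algebraic inverse).
#'
#' @param distanceKm crossing distance, km (> 0)
#' @param airspeed airspeed, m/s
#' @param endurance endurance, hours
#' @return headwind magnitude, m/s
#' @examples
#' maxHeadwind(1500, 10, 84)  # ~5 m/s for the 1500-km crossing
#' @export
maxHeadwind <- function(distanceKm, airspeed, endurance) {
  stopifnot(distanceKm > 0, airspeed > 0, endurance > 0)
  airspeed - distanceKm / (endurance * 3.6)
}

#' Crossing time at a given groundspeed
#'
#' @param distanceKm distance, km (>= 0)
#' @param groundspeed groundspeed, m/s (> 0)
#' @return duration in hours
#' @examples
#' crossingTimeH(1500, 15)  # ~27.8 h
#' @export
crossingTimeH <- function(distanceKm, groundspeed) {
  if (any(groundspeed <= 0)) stop("groundspeed must be positive")
  stopifnot(all(distanceKm >= 0))
  distanceKm / (groundspeed * 3.6)
}
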