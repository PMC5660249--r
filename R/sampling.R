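# Wind conventions, IDW interpolation, the tailwind statistic, and
# per-night wind summaries.

#' Construct a geographic point
#'
#' Longitudes are normalized to [-180, 180); latitudes must lie in [-90, 90].
#'
#' @param lat latitude, degrees north
#' @param lon longitude, degrees east
#' @return named numeric vector \code{c(lat, lon)}
#' @export
geoPoint <- function(lat, lon) {
  stopifnot(is.finite(lat), is.finite(lon))
  if (lat < -90 || lat > 90) stop("latitude must lie in [-90, 90]")
  lon <- ((lon + 180) %% 360) - 180
  c(lat = lat, lon = lon)
}

#' Convert wind components to speed/direction and back
#'
#' Directions are degrees clockwise from geographic north in the "toward"
#' convention (the direction the wind is going). A zero vector gets
#' direction 0 by convention; this is harmless downstream because speed
#' multiplies every cosine.
#'
#' @param u eastward component, m/s (vectorized)
#' @param v northward component, m/s
#' @return \code{uvToWind}: data.frame with columns \code{speed},
#'   \code{dirToward}. \code{windToUV}: data.frame with columns \code{u},
#'   \code{v}.
#' @examples
#' uvToWind(0, 5)   # speed 5, toward 0 (north)
#' uvToWind(5, 0)   # speed 5, toward 90 (east)
#' @export
uvToWind <- function(u, v) {
  speed <- sqrt(u^2 + v^2)
  dir <- ifelse(speed == 0, 0, .wrap360(.rad2deg(atan2(u, v))))
  data.frame(speed = speed, dirToward = dir)
}

#' @rdname uvToWind
#' @param speed wind speed, m/s (>= 0)
#' @param dirToward direction toward, degrees clockwise from north
#' @export
windToUV <- function(speed, dirToward) {
  if (is.data.frame(speed)) {
    dirToward <- speed$dirToward
    speed <- speed$speed
  }
  stopifnot(all(speed >= 0))
  data.frame(u = speed * sin(.deg2rad(dirToward)),
             v = speed * cos(.deg2rad(dirToward)))
}

#' Tailwind ("wind profit") along a reference direction
#'
#' The signed component of the wind along a reference travel direction:
#' \code{cos(ref - windDir) * speed}, positive when the wind supports travel
#' toward the reference direction. Winds with tailwind > 0 are "supportive";
#' tailwinds <= 0 are headwinds.
#'
#' @param speed wind speed, m/s, or a data.frame from \code{\link{uvToWind}}
#' @param dirToward wind direction toward, degrees
#' @param referenceDir reference travel direction, degrees toward
#' @return tailwind in m/s (vectorized over all arguments)
#' @examples
#' tailwind(6, 180, 180)  # +6, aligned
#' tailwind(6, 90, 180)   #  0, pure crosswind
#' tailwind(6, 0, 180)    # -6, opposing
#' @export
tailwind <- function(speed, dirToward, referenceDir) {
  if (is.data.frame(speed)) {
    referenceDir <- dirToward
    dirToward <- speed$dirToward
    speed <- speed$speed
  }
  cos(.deg2rad(referenceDir - dirToward)) * speed
}

#' Tailwind directly from u/v components
#'
#' Equivalent to \code{tailwind(uvToWind(u, v), referenceDir)}: the
#' projection \code{u sin(ref) + v cos(ref)}.
#'
#' @param u,v wind components, m/s
#' @param referenceDir reference travel direction, degrees toward
#' @export
tailwindUV <- function(u, v, referenceDir) {
  u * sin(.deg2rad(referenceDir)) + v * cos(.deg2rad(referenceDir))
}

#' Is a tailwind supportive?
#'
#' Supportive tailwinds are strictly greater than 0 m/s; values less than or
#' equal to 0 are headwinds. The same threshold is shared by the
#' forecasting-consistency metrics.
#'
#' @param tw tailwind, m/s
#' @export
isSupportive <- function(tw) tw > SUPPORT_THRESHOLD

.extentError <- function(msg) {
  stop(structure(
    class = c("gulfcross_extent_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# index of the cell [i, i+1] bracketing x in ascending coords; error if out
.bracket <- function(x, coords, what) {
  n <- length(coords)
  if (x < coords[1] || x > coords[n]) {
    .extentError(sprintf("%s %s outside grid extent [%s, %s]", what,
      format(x), format(coords[1]), format(coords[n])))
  }
  i <- findInterval(x, coords)
  if (i >= n) i <- n - 1
  i
}

# spatial IDW over the 4 surrounding nodes of one time slab
.idwSlab <- function(grid, it, lat, lon, ilat, ilon, power) {
  nlat <- c(grid@lats[ilat], grid@lats[ilat], grid@lats[ilat + 1],
    grid@lats[ilat + 1])
  nlon <- c(grid@lons[ilon], grid@lons[ilon + 1], grid@lons[ilon],
    grid@lons[ilon + 1])
  d <- geosphere::distHaversine(cbind(lon, lat), cbind(nlon, nlat),
    r = EARTH_RADIUS_M)
  uu <- c(grid@u[it, ilat, ilon], grid@u[it, ilat, ilon + 1],
    grid@u[it, ilat + 1, ilon], grid@u[it, ilat + 1, ilon + 1])
  vv <- c(grid@v[it, ilat, ilon], grid@v[it, ilat, ilon + 1],
    grid@v[it, ilat + 1, ilon], grid@v[it, ilat + 1, ilon + 1])
  hit <- which(d < 1e-6)
  if (length(hit)) return(c(u = uu[hit[1]], v = vv[hit[1]]))
  w <- 1 / d^power
  c(u = sum(w * uu) / sum(w), v = sum(w * vv) / sum(w))
}

#' Inverse-distance-weighted wind at a point and time
#'
#' Interpolates the u and v components separately from the four grid nodes
#' surrounding the query point, with weights 1/d^power where d is the
#' great-circle distance (m) to each node, then linearly in time between the
#' two bracketing 3-h snapshots. Queries exactly on a node and snapshot
#' return the stored values.
#'
#' @param grid a \linkS4class{WindGrid}
#' @param lat,lon query position, degrees
#' @param time query instant (POSIXct UTC)
#' @param power IDW exponent; the default 1 gives weights 1/d. Configurable
#'   because only "inverse-weighted distance" is specified by convention.
#' @return named numeric \code{c(u, v)} in m/s
#' @seealso \code{\link{uvToWind}} to convert to speed/direction
#' @export
idwWind <- function(grid, lat, lon, time, power = 1) {
  time <- as.POSIXct(time, tz = "UTC")
  if (length(grid@lats) < 2 || length(grid@lons) < 2) {
    stop("grid must have at least 2 nodes in each spatial dimension")
  }
  ilat <- .bracket(lat, grid@lats, "latitude")
  ilon <- .bracket(lon, grid@lons, "longitude")
  tnum <- as.numeric(time)
  tgrid <- as.numeric(grid@times)
  nt <- length(tgrid)
  if (tnum < tgrid[1] || tnum > tgrid[nt]) {
    .extentError("time outside grid extent")
  }
  it <- findInterval(tnum, tgrid)
  if (tnum == tgrid[it]) {
    return(.idwSlab(grid, it, lat, lon, ilat, ilon, power))
  }
  w1 <- .idwSlab(grid, it, lat, lon, ilat, ilon, power)
  w2 <- .idwSlab(grid, it + 1, lat, lon, ilat, ilon, power)
  frac <- (tnum - tgrid[it]) / (tgrid[it + 1] - tgrid[it])
  (1 - frac) * w1 + frac * w2
}

#' Nightly wind summary at a site
#'
#' Summarizes the winds of one night at a fixed site the way the arrival
#' analyses require: tailwind is evaluated at the five 3-hourly UTC instants
#' 00:00, 03:00, ..., 12:00 and against each of five reference departure
#' directions; \code{meanTailwind} averages all 25 values, and \code{slope}
#' is the ordinary-least-squares slope of the five per-instant
#' direction-averaged tailwinds against hours elapsed (0, 3, 6, 9, 12).
#'
#' A night is labelled by its local evening date: the night of date D runs
#' from the evening of D to the morning of D+1, so its five UTC samples fall
#' on calendar date D+1 (the site sits west of Greenwich) and its departure
#' twilight is the evening civil twilight of local date D.
#'
#' @param grid a \linkS4class{WindGrid}
#' @param site \code{c(lat, lon)} (see \code{\link{geoPoint}})
#' @param date the night's local evening date (\code{Date})
#' @param referenceDirs reference directions, degrees toward; the nightly
#'   mean is invariant to their order
#' @param twilight optional explicit departure instant (POSIXct UTC); if
#'   NULL, computed by \code{\link{civilTwilight}} for \code{date}
#' @param power IDW exponent passed to \code{\link{idwWind}}
#' @return list with \code{date}, \code{meanTailwind}, \code{slope} (m/s per
#'   hour), \code{twilightTailwind}, and \code{missing} (TRUE when any of
#'   the five snapshots falls outside the grid; such nights are excluded
#'   downstream)
#' @export
nightlySummary <- function(grid, site, date,
                           referenceDirs = c(120, 150, 180, 210, 240),
                           twilight = NULL, power = 1) {
  date <- as.Date(date)
  sampleTimes <- as.POSIXct(paste(date + 1, sprintf("%02d:00:00", c(0, 3, 6, 9, 12))),
    tz = "UTC")
  perTime <- rep(NA_real_, 5)
  missing <- FALSE
  for (k in seq_along(sampleTimes)) {
    uv <- tryCatch(
      idwWind(grid, site["lat"], site["lon"], sampleTimes[k], power = power),
      gulfcross_extent_error = function(e) NULL
    )
    if (is.null(uv)) {
      missing <- TRUE
      break
    }
    perTime[k] <- mean(tailwindUV(uv["u"], uv["v"], referenceDirs))
  }
  if (missing) {
    return(list(date = date, meanTailwind = NA_real_, slope = NA_real_,
      twilightTailwind = NA_real_, missing = TRUE))
  }
  hours <- c(0, 3, 6, 9, 12)
  slope <- sum((hours - mean(hours)) * (perTime - mean(perTime))) /
    sum((hours - mean(hours))^2)
  if (is.null(twilight)) {
    twilight <- civilTwilight(site["lat"], site["lon"], date)
  }
  twTail <- tryCatch({
    uv <- idwWind(grid, site["lat"], site["lon"], twilight, power = power)
    mean(tailwindUV(uv["u"], uv["v"], referenceDirs))
  }, gulfcross_extent_error = function(e) NA_real_)
  list(date = date, meanTailwind = mean(perTime), slope = slope,
    twilightTailwind = twTail, missing = FALSE)
}
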