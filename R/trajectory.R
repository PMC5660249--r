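# Forward trajectory model: wind-triangle heading solution, hourly
# loxodrome stepping under interpolated winds, and the five-track night.

#' Trajectory-model configuration
#'
#' Defaults mirror the study design: tracks launch from the Ft. Morgan
#' peninsula origin (30.2 N, 88.0 W) at civil twilight toward five
#' candidate departure directions, hold a constant heading (solved from the
#' wind at the first step) and a constant 10 m/s airspeed at a nominal 1-km
#' altitude, advance in 1-h loxodrome steps, and stop on reaching land, on
#' exhausting 45 steps, or on leaving the data domain.
#'
#' @param origin \code{c(lat, lon)} launch point
#' @param departureDirs candidate track directions, degrees toward
#' @param airspeed constant airspeed, m/s (> 0)
#' @param stepHours step length, hours
#' @param maxSteps maximum number of one-hour steps per track
#' @param altitude metadata label only (a single wind level is used)
#' @param idwPower IDW exponent for wind sampling
#' @return a validated config (list of class \code{trajectoryConfig})
#' @export
trajectoryConfig <- function(origin = c(lat = 30.2, lon = -88.0),
                             departureDirs = c(120, 150, 180, 210, 240),
                             airspeed = 10, stepHours = 1, maxSteps = 45,
                             altitude = "1 km", idwPower = 1) {
  stopifnot(airspeed > 0, maxSteps >= 1, stepHours > 0)
  structure(list(
    origin = geoPoint(origin[["lat"]], origin[["lon"]]),
    departureDirs = departureDirs, airspeed = airspeed,
    stepHours = stepHours, maxSteps = as.integer(maxSteps),
    altitude = altitude, idwPower = idwPower
  ), class = "trajectoryConfig")
}

.infeasibleError <- function(msg) {
  stop(structure(
    class = c("gulfcross_infeasible_heading", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Wind-triangle heading for a target track direction
#'
#' The heading a bird must hold so that its air vector plus the wind vector
#' points along the target track direction: \code{heading = target -
#' asin(crosswind / airspeed)}, where crosswind is the wind component
#' perpendicular to the target. Infeasible when the crosswind exceeds the
#' airspeed (the bird cannot hold that track).
#'
#' @param targetDir intended track direction, degrees toward
#' @param windSpeed,windDir wind speed (m/s) and direction toward (degrees),
#'   or a data.frame from \code{\link{uvToWind}} as \code{windSpeed}
#' @param airspeed airspeed, m/s (> 0)
#' @return heading, degrees in [0, 360)
#' @examples
#' solveHeading(180, 0, 0, 10)   # no wind: heading = track = 180
#' solveHeading(180, 5, 90, 10)  # 5 m/s crosswind from the left: 210
#' @export
solveHeading <- function(targetDir, windSpeed, windDir, airspeed) {
  if (is.data.frame(windSpeed)) {
    airspeed <- windDir
    windDir <- windSpeed$dirToward
    windSpeed <- windSpeed$speed
  }
  stopifnot(airspeed > 0)
  cross <- windSpeed * sin(.deg2rad(windDir - targetDir))
  if (abs(cross) > airspeed) {
    .infeasibleError(sprintf(
      "crosswind %.2f m/s exceeds airspeed %.2f m/s for track %g deg",
      cross, airspeed, targetDir))
  }
  .wrap360(targetDir - .rad2deg(asin(cross / airspeed)))
}

#' Advance one loxodrome step under wind
#'
#' Vector-sums the air vector (airspeed at the fixed heading) with the wind
#' vector to get the ground vector, then advances the position along the
#' rhumb line (constant bearing) on a sphere of radius 6371 km for
#' \code{groundspeed * dtHours} metres.
#'
#' @param lat,lon current position, degrees
#' @param heading body-axis orientation, degrees
#' @param airspeed airspeed, m/s
#' @param u,v wind components at the current position/time, m/s
#' @param dtHours step duration, hours
#' @return list with \code{lat}, \code{lon} (new position),
#'   \code{groundspeed} (m/s), \code{trackDir} (degrees)
#' @export
trackStep <- function(lat, lon, heading, airspeed, u, v, dtHours = 1) {
  stopifnot(dtHours > 0)
  gu <- airspeed * sin(.deg2rad(heading)) + u
  gv <- airspeed * cos(.deg2rad(heading)) + v
  ground <- uvToWind(gu, gv)
  dist <- ground$speed * dtHours * 3600
  if (dist == 0) {
    return(list(lat = lat, lon = lon, groundspeed = 0,
      trackDir = ground$dirToward))
  }
  p <- geosphere::destPointRhumb(c(lon, lat), ground$dirToward, dist,
    r = EARTH_RADIUS_M)
  list(lat = p[1, 2], lon = p[1, 1], groundspeed = ground$speed,
    trackDir = ground$dirToward)
}

#' Simulate one trans-Gulf track
#'
#' Forward-simulates a single flight: the heading is solved once from the
#' interpolated wind at the origin at the start time and held constant
#' thereafter; each one-hour step samples the wind at the step's start
#' position and time, vector-sums it with the air vector, and advances the
#' position along the resulting rhumb bearing. The simulation stops when at
#' least one of the four raster nodes nearest the new position is land
#' (\code{"reached_land"}), when \code{maxSteps} steps have been flown
#' (\code{"max_steps"}), or when the track leaves the spatial or temporal
#' extent of the wind or mask data (\code{"domain_exit"}).
#'
#' Point \code{i} of the returned \linkS4class{Track} is the state at the
#' start of step \code{i} (so a track that lands in one step has one point
#' and one wind sample); per-step tailwind is computed against the track's
#' departure direction.
#'
#' @param grid a \linkS4class{WindGrid}
#' @param mask a \linkS4class{LandMask}
#' @param cfg a \code{\link{trajectoryConfig}}
#' @param departureDir intended track direction at departure, degrees
#' @param startTime launch instant (POSIXct UTC), within the grid
#' @return a \linkS4class{Track}; an infeasible first-step heading raises a
#'   condition of class \code{gulfcross_infeasible_heading}
#' @export
simulateTrack <- function(grid, mask, cfg, departureDir, startTime) {
  startTime <- as.POSIXct(startTime, tz = "UTC")
  lat <- cfg$origin[["lat"]]
  lon <- cfg$origin[["lon"]]
  t <- startTime
  wind0 <- idwWind(grid, lat, lon, t, power = cfg$idwPower)
  w0 <- uvToWind(wind0[["u"]], wind0[["v"]])
  heading <- solveHeading(departureDir, w0$speed, w0$dirToward, cfg$airspeed)

  pts <- vector("list", cfg$maxSteps)
  termination <- "max_steps"
  endPos <- c(lat = lat, lon = lon)
  uv <- wind0
  for (i in seq_len(cfg$maxSteps)) {
    if (i > 1) {
      uv <- tryCatch(
        idwWind(grid, lat, lon, t, power = cfg$idwPower),
        gulfcross_extent_error = function(e) NULL
      )
      if (is.null(uv)) {
        termination <- "domain_exit"
        pts <- pts[seq_len(i - 1)]
        break
      }
    }
    w <- uvToWind(uv[["u"]], uv[["v"]])
    adv <- trackStep(lat, lon, heading, cfg$airspeed, uv[["u"]], uv[["v"]],
      cfg$stepHours)
    pts[[i]] <- data.frame(
      time = t, lat = lat, lon = lon, u = uv[["u"]], v = uv[["v"]],
      windSpeed = w$speed, windDir = w$dirToward,
      groundspeed = adv$groundspeed, trackDir = adv$trackDir,
      tailwind = tailwindUV(uv[["u"]], uv[["v"]], departureDir)
    )
    lat <- adv$lat
    lon <- adv$lon
    t <- t + cfg$stepHours * 3600
    endPos <- c(lat = lat, lon = lon)
    landed <- tryCatch(reachedLand(mask, lat, lon),
      gulfcross_extent_error = function(e) NA)
    if (is.na(landed)) {
      termination <- "domain_exit"
      pts <- pts[seq_len(i)]
      break
    }
    if (landed) {
      termination <- "reached_land"
      pts <- pts[seq_len(i)]
      break
    }
  }
  pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  new("Track",
    departureDir = departureDir, heading = heading, airspeed = cfg$airspeed,
    points = pts, termination = termination,
    meanTailwind = mean(pts$tailwind), endPosition = endPos
  )
}

#' Simulate the five tracks of one night
#'
#' Launches one track per candidate departure direction from the origin at
#' the night's civil twilight (the evening of \code{date}), and summarizes
#' them: \code{gulfMeanTailwind} is the mean over tracks of each track's
#' mean per-step tailwind (the Gulf-wide wind profit a migrant would
#' experience en route), and \code{departureTailwind} is the mean over
#' tracks of the first-step tailwind (the local wind profit at departure).
#' Tracks whose first-step heading is infeasible are dropped; a night with
#' fewer than five feasible tracks is flagged invalid.
#'
#' @param grid a \linkS4class{WindGrid}
#' @param mask a \linkS4class{LandMask}
#' @param cfg a \code{\link{trajectoryConfig}}
#' @param date the night's local evening date (\code{Date})
#' @param twilight optional explicit launch instant (POSIXct UTC)
#' @return a \linkS4class{NightSim}
#' @export
simulateNight <- function(grid, mask, cfg, date, twilight = NULL) {
  date <- as.Date(date)
  if (is.null(twilight)) {
    twilight <- civilTwilight(cfg$origin[["lat"]], cfg$origin[["lon"]], date)
  } else {
    twilight <- as.POSIXct(twilight, tz = "UTC")
  }
  tracks <- list()
  for (dir in cfg$departureDirs) {
    tr <- tryCatch(
      simulateTrack(grid, mask, cfg, dir, twilight),
      gulfcross_infeasible_heading = function(e) NULL
    )
    if (!is.null(tr)) tracks[[length(tracks) + 1]] <- tr
  }
  perTrackMean <- vapply(tracks, meanTailwind, numeric(1))
  firstStep <- vapply(tracks, function(tr) tr@points$tailwind[1], numeric(1))
  new("NightSim",
    date = date, twilight = twilight, tracks = tracks,
    gulfMeanTailwind = if (length(tracks)) mean(perTrackMean) else NA_real_,
    departureTailwind = if (length(tracks)) mean(firstStep) else NA_real_,
    valid = length(tracks) == length(cfg$departureDirs)
  )
}
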