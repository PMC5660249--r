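# Synthetic reanalysis-like wind fields: mean flow plus spatially smoothed,
# temporally AR(1) anomalies, on a regular 3-hourly / fixed-km grid.

#' Configuration for the synthetic wind-field generator
#'
#' The generated field is a constant mean flow plus an anomaly field built
#' from white noise smoothed with a Gaussian kernel of width
#' \code{spatialCorrKm} and evolved through time as an AR(1) process with
#' coefficient \code{temporalAr1}. The anomaly field is normalized cell by
#' cell so its marginal standard deviation equals \code{anomalySd} exactly
#' (including at grid edges), and the u and v anomalies are generated
#' independently.
#'
#' @param latRange,lonRange numeric length-2 domain bounds, degrees
#' @param dateRange length-2 \code{Date} (or coercible); snapshots run from
#'   00:00 UTC on the first date to 21:00 UTC on the last, every 3 h
#' @param resolutionKm horizontal grid spacing, km (default 32, matching a
#'   regional reanalysis)
#' @param meanFlowSpeed,meanFlowDir mean flow, m/s and degrees toward
#' @param anomalySd marginal standard deviation of each anomaly component,
#'   m/s (>= 0)
#' @param spatialCorrKm Gaussian smoothing length of the anomalies, km
#' @param temporalAr1 lag-1 (3-h) autocorrelation of each cell's anomaly
#'   series, in [0, 1)
#' @param altitude altitude label carried as metadata (a single wind level
#'   is modelled; winds at nearby altitudes are strongly correlated in the
#'   reanalysis this emulates)
#' @param seed integer seed; identical config + seed gives a bitwise
#'   identical grid
#' @return a validated config (list of class \code{windSimConfig})
#' @export
windSimConfig <- function(latRange = c(15, 32), lonRange = c(-100, -75),
                          dateRange = as.Date(c("2010-09-01", "2010-11-01")),
                          resolutionKm = 32,
                          meanFlowSpeed = 2, meanFlowDir = 231,
                          anomalySd = 4, spatialCorrKm = 300,
                          temporalAr1 = 0.7, altitude = "1 km",
                          seed = NULL) {
  stopifnot(length(latRange) == 2, length(lonRange) == 2)
  latRange <- sort(as.numeric(latRange))
  lonRange <- sort(as.numeric(lonRange))
  dateRange <- as.Date(dateRange)
  if (diff(latRange) <= 0 || diff(lonRange) <= 0) {
    stop("empty spatial domain")
  }
  if (dateRange[2] < dateRange[1]) stop("empty time domain")
  if (anomalySd < 0) stop("anomalySd must be >= 0")
  if (temporalAr1 < 0 || temporalAr1 >= 1) {
    stop("temporalAr1 must lie in [0, 1)")
  }
  if (resolutionKm <= 0) stop("resolutionKm must be positive")
  structure(list(
    latRange = latRange, lonRange = lonRange, dateRange = dateRange,
    resolutionKm = resolutionKm, meanFlowSpeed = meanFlowSpeed,
    meanFlowDir = meanFlowDir, anomalySd = anomalySd,
    spatialCorrKm = spatialCorrKm, temporalAr1 = temporalAr1,
    altitude = altitude, seed = seed
  ), class = "windSimConfig")
}

# cell-center coordinates covering [lo, hi] at the given degree step
.cellCenters <- function(lo, hi, step) {
  if (lo + step / 2 > hi) stop("domain too small for the requested resolution")
  x <- seq(lo + step / 2, hi, by = step)
  if (length(x) < 2) stop("domain too small for the requested resolution")
  x
}

#' @rdname generateWindField
#' @export
gridCoords <- function(latRange, lonRange, resolutionKm) {
  latStep <- resolutionKm / KM_PER_DEG
  lonStep <- resolutionKm / (KM_PER_DEG * cos(.deg2rad(mean(latRange))))
  list(lats = .cellCenters(latRange[1], latRange[2], latStep),
       lons = .cellCenters(lonRange[1], lonRange[2], lonStep))
}

# row-normalized banded Gaussian smoothing matrix (n x n), sd in cells
.gaussSmoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  h <- max(1L, ceiling(3 * sigma))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    w <- exp(-0.5 * ((j - i) / sigma)^2)
    A[i, j] <- w / sum(w)
  }
  A
}

# one spatially smoothed N(0,1)-marginal field (nlat x nlon)
.smoothedNoise <- function(A, B, normFac, nlat, nlon) {
  (A %*% matrix(rnorm(nlat * nlon), nlat, nlon) %*% t(B)) / normFac
}

#' Generate a synthetic gridded wind field
#'
#' Builds a \linkS4class{WindGrid} whose u and v components are the mean
#' flow plus anomalies: per time slab, white noise smoothed by a Gaussian
#' kernel of width \code{spatialCorrKm} (giving spatially smooth fields),
#' chained through time as \code{F_t = ar1 * F_(t-1) + sqrt(1 - ar1^2) *
#' Z_t} (giving each cell a stationary AR(1) series with lag-1
#' autocorrelation \code{temporalAr1} and marginal SD \code{anomalySd}).
#' With \code{anomalySd = 0} every cell carries the mean flow exactly.
#'
#' \code{gridCoords} exposes the cell-center coordinate construction shared
#' with \code{\link{generateGulfMask}}.
#'
#' @param config a \code{\link{windSimConfig}}
#' @param latRange,lonRange,resolutionKm see \code{\link{windSimConfig}}
#' @return a \linkS4class{WindGrid}
#' @export
generateWindField <- function(config) {
  stopifnot(inherits(config, "windSimConfig"))
  coords <- gridCoords(config$latRange, config$lonRange, config$resolutionKm)
  times <- seq(
    as.POSIXct(config$dateRange[1], tz = "UTC"),
    as.POSIXct(config$dateRange[2], tz = "UTC") + 21 * 3600,
    by = 3 * 3600
  )
  nlat <- length(coords$lats)
  nlon <- length(coords$lons)
  nt <- length(times)
  meanU <- config$meanFlowSpeed * sin(.deg2rad(config$meanFlowDir))
  meanV <- config$meanFlowSpeed * cos(.deg2rad(config$meanFlowDir))
  u <- array(meanU, dim = c(nt, nlat, nlon))
  v <- array(meanV, dim = c(nt, nlat, nlon))
  if (config$anomalySd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    sigma <- config$spatialCorrKm / config$resolutionKm
    A <- .gaussSmoother(nlat, sigma)
    B <- .gaussSmoother(nlon, sigma)
    # per-cell SD of smoothed unit noise, so marginal SD is exact at edges too
    normFac <- sqrt(outer(rowSums(A^2), rowSums(B^2)))
    phi <- config$temporalAr1
    innovScale <- sqrt(1 - phi^2)
    fu <- .smoothedNoise(A, B, normFac, nlat, nlon)
    fv <- .smoothedNoise(A, B, normFac, nlat, nlon)
    u[1, , ] <- meanU + config$anomalySd * fu
    v[1, , ] <- meanV + config$anomalySd * fv
    for (t in seq_len(nt)[-1]) {
      fu <- phi * fu + innovScale * .smoothedNoise(A, B, normFac, nlat, nlon)
      fv <- phi * fv + innovScale * .smoothedNoise(A, B, normFac, nlat, nlon)
      u[t, , ] <- meanU + config$anomalySd * fu
      v[t, , ] <- meanV + config$anomalySd * fv
    }
  }
  windGrid(coords$lats, coords$lons, times, u, v,
    meta = list(resolutionKm = config$resolutionKm,
      altitude = config$altitude))
}
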