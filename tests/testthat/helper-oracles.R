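# Independent oracles and small in-code fixtures shared across tests.
# Every oracle is implemented from first principles, separately from the
# package's own code paths.

R_EARTH <- 6371000

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# great-circle distance, atan2 form (different formulation from the
# package's haversine route)
oracleDist <- function(lat1, lon1, lat2, lon2) {
  p1 <- deg2rad(lat1); p2 <- deg2rad(lat2)
  dl <- deg2rad(lon2 - lon1)
  a <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  R_EARTH * 2 * atan2(sqrt(a), sqrt(1 - a))
}

# rhumb-line destination on the R = 6371 km sphere, hand-rolled
oracleRhumb <- function(lat, lon, bearingDeg, distM) {
  th <- deg2rad(bearingDeg)
  phi1 <- deg2rad(lat)
  delta <- distM / R_EARTH
  dphi <- delta * cos(th)
  phi2 <- phi1 + dphi
  dpsi <- log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  q <- if (abs(dpsi) > 1e-12) dphi / dpsi else cos(phi1)
  dlam <- delta * sin(th) / q
  c(lat = rad2deg(phi2), lon = lon + rad2deg(dlam))
}

# brute-force IDW over the 4 surrounding nodes + linear time interpolation
oracleIDW <- function(grid, lat, lon, time, power = 1) {
  la <- lats(grid); lo <- lons(grid); tt <- as.numeric(timesUTC(grid))
  ilat <- findInterval(lat, la); if (ilat >= length(la)) ilat <- length(la) - 1
  ilon <- findInterval(lon, lo); if (ilon >= length(lo)) ilon <- length(lo) - 1
  slab <- function(it) {
    acc <- c(u = 0, v = 0); wsum <- 0
    for (i in c(ilat, ilat + 1)) for (j in c(ilon, ilon + 1)) {
      d <- oracleDist(lat, lon, la[i], lo[j])
      if (d < 1e-6) return(c(u = uwind(grid)[it, i, j], v = vwind(grid)[it, i, j]))
      w <- 1 / d^power
      acc <- acc + w * c(uwind(grid)[it, i, j], vwind(grid)[it, i, j])
      wsum <- wsum + w
    }
    acc / wsum
  }
  tn <- as.numeric(as.POSIXct(time, tz = "UTC"))
  it <- findInterval(tn, tt)
  if (tn == tt[it]) return(slab(it))
  f <- (tn - tt[it]) / (tt[it + 1] - tt[it])
  (1 - f) * slab(it) + f * slab(it + 1)
}

# independent solar geometry (Cooper declination + 9.87-form equation of
# time), for checking civil twilight
oracleTwilightUTCmin <- function(lat, lon, date, zenith = 96) {
  n <- as.integer(format(as.Date(date), "%j"))
  decl <- deg2rad(23.44 * sin(2 * pi * (284 + n) / 365))
  B <- 2 * pi * (n - 81) / 364
  eqt <- 9.87 * sin(2 * B) - 7.53 * cos(B) - 1.5 * sin(B)
  phi <- deg2rad(lat)
  cosha <- cos(deg2rad(zenith)) / (cos(phi) * cos(decl)) - tan(phi) * tan(decl)
  ha <- rad2deg(acos(cosha))
  720 - 4 * (lon - ha) - eqt
}

# --- fixtures ---------------------------------------------------------------

# grid with wind given by functions u(t, lat, lon), v(t, lat, lon); t is the
# snapshot index
functionGrid <- function(ufun, vfun,
                         lats = seq(20, 31, by = 1.5),
                         lons = seq(-95, -80, by = 1.5),
                         nTimes = 16,
                         start = as.POSIXct("2010-09-01 00:00:00", tz = "UTC")) {
  times <- start + (seq_len(nTimes) - 1) * 3 * 3600
  u <- array(0, c(nTimes, length(lats), length(lons)))
  v <- array(0, c(nTimes, length(lats), length(lons)))
  for (t in seq_len(nTimes)) for (i in seq_along(lats)) for (j in seq_along(lons)) {
    u[t, i, j] <- ufun(t, lats[i], lons[j])
    v[t, i, j] <- vfun(t, lats[i], lons[j])
  }
  windGrid(lats, lons, times, u, v)
}

uniformGrid <- function(u0, v0, ...) {
  functionGrid(function(t, la, lo) u0, function(t, la, lo) v0, ...)
}

# big sparse all-water / custom masks
waterMask <- function(lats = seq(-10, 40, by = 2), lons = seq(-120, -60, by = 2)) {
  landMask(lats, lons, matrix(FALSE, length(lats), length(lons)))
}

# default study-domain grid/mask for night simulations (coarse, fast)
studyGrid <- function(nDays = 4, seed = 1, anomalySd = 2, ...) {
  generateWindField(windSimConfig(
    latRange = c(15, 32), lonRange = c(-100, -75),
    dateRange = as.Date(c("2010-09-01", "2010-09-01")) + c(0, nDays),
    resolutionKm = 96, anomalySd = anomalySd, spatialCorrKm = 200,
    seed = seed, ...))
}

studyMask <- function() generateGulfMask(c(15, 32), c(-100, -75), 96)
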