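# Plain-text I/O: long-format CSV for wind grids, raster CSV for masks,
# tabular CSV for night records. All round-trip losslessly (numeric values
# are written with 17 significant digits).

.fmtNum <- function(x) sprintf("%.17g", x)

#' Wind-grid CSV I/O (long format)
#'
#' Writes a \linkS4class{WindGrid} as a long-format CSV with columns
#' \code{time, lat, lon, u, v} (times ISO-8601 UTC), and reads it back. The
#' round trip is lossless: numeric values are written with full double
#' precision and coordinates are reconstructed from the unique sorted
#' values.
#'
#' @param grid a \linkS4class{WindGrid}
#' @param path file path
#' @return \code{readWindCSV} returns a \linkS4class{WindGrid};
#'   \code{writeWindCSV} returns \code{path} invisibly
#' @export
writeWindCSV <- function(grid, path) {
  nt <- length(grid@times)
  nlat <- length(grid@lats)
  nlon <- length(grid@lons)
  df <- data.frame(
    time = rep(format(grid@times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      times = nlat * nlon),
    lat = .fmtNum(rep(rep(grid@lats, each = nt), times = nlon)),
    lon = .fmtNum(rep(grid@lons, each = nt * nlat)),
    u = .fmtNum(as.vector(grid@u)),
    v = .fmtNum(as.vector(grid@v))
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeWindCSV
#' @export
readWindCSV <- function(path) {
  df <- read.csv(path, colClasses = c(time = "character"))
  times <- sort(unique(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ",
    tz = "UTC")))
  latsv <- sort(unique(df$lat))
  lonsv <- sort(unique(df$lon))
  nt <- length(times)
  nlat <- length(latsv)
  nlon <- length(lonsv)
  it <- match(as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    times)
  ilat <- match(df$lat, latsv)
  ilon <- match(df$lon, lonsv)
  u <- array(NA_real_, c(nt, nlat, nlon))
  v <- array(NA_real_, c(nt, nlat, nlon))
  idx <- cbind(it, ilat, ilon)
  u[idx] <- df$u
  v[idx] <- df$v
  if (anyNA(u) || anyNA(v)) stop("wind CSV does not cover a full grid")
  windGrid(latsv, lonsv, times, u, v)
}

#' Land-mask CSV I/O
#'
#' Raster CSV with columns \code{lat, lon, is_land}; lossless round trip.
#'
#' @param mask a \linkS4class{LandMask}
#' @param path file path
#' @export
writeMaskCSV <- function(mask, path) {
  df <- data.frame(
    lat = .fmtNum(rep(mask@lats, times = length(mask@lons))),
    lon = .fmtNum(rep(mask@lons, each = length(mask@lats))),
    is_land = as.integer(as.vector(mask@isLand))
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMaskCSV
#' @export
readMaskCSV <- function(path) {
  df <- read.csv(path)
  latsv <- sort(unique(df$lat))
  lonsv <- sort(unique(df$lon))
  m <- matrix(NA, length(latsv), length(lonsv))
  m[cbind(match(df$lat, latsv), match(df$lon, lonsv))] <- df$is_land == 1
  if (anyNA(m)) stop("mask CSV does not cover a full raster")
  landMask(latsv, lonsv, m)
}

#' Night-record CSV I/O
#'
#' Tabular CSV with columns \code{date, year, period, stopover, departure,
#' available, tailwind_night_mean, tailwind_twilight}.
#'
#' @param records a night-record data.frame (see
#'   \code{\link{generateBirdNights}})
#' @param path file path
#' @export
writeNightCSV <- function(records, path) {
  out <- records
  out$date <- format(as.Date(records$date))
  num <- c("tailwind_night_mean", "tailwind_twilight")
  for (col in intersect(num, names(out))) out[[col]] <- .fmtNum(out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeNightCSV
#' @export
readNightCSV <- function(path) {
  df <- read.csv(path, colClasses = c(date = "character"))
  df$date <- as.Date(df$date)
  df
}
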