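# Land-water mask rasterization and the reached-land predicate.

#' Stylized Gulf-of-Mexico coastline polygons
#'
#' Loads the synthetic coastline fixture shipped with the package: a
#' hand-drawn, deliberately coarse tracing of the land surrounding the Gulf
#' of Mexico (mainland North/Central America plus Cuba), intended only to
#' give simulated trans-Gulf tracks realistic landfall geometry. Cells whose
#' centers fall inside any polygon are land.
#'
#' @return list of data.frames with columns \code{lon}, \code{lat}, one per
#'   closed polygon
#' @export
gulfCoastPolygon <- function() {
  path <- system.file("extdata", "gulf_coast_synthetic.csv",
    package = "gulfcross", mustWork = TRUE)
  df <- read.csv(path)
  split(df[c("lon", "lat")], df$polygon)
}

.asPolygonList <- function(coastPolygon) {
  if (is.null(coastPolygon)) return(list())
  if (is.data.frame(coastPolygon)) coastPolygon <- list(coastPolygon)
  for (p in coastPolygon) {
    if (nrow(p) == 0) next
    if (nrow(unique(p[c("lon", "lat")])) < 3) {
      stop("degenerate coast polygon (fewer than 3 distinct vertices)")
    }
  }
  coastPolygon
}

#' Rasterize a coastline polygon to a land-water mask
#'
#' Builds a \linkS4class{LandMask} on the same cell-center grid convention
#' as \code{\link{generateWindField}}: a cell is land iff its center falls
#' inside (or on the boundary of) any supplied polygon. The rasterization
#' depends only on cell centers, so it is idempotent and independent of
#' traversal order.
#'
#' @param latRange,lonRange domain bounds, degrees
#' @param resolutionKm raster spacing, km (default 32)
#' @param coastPolygon a data.frame with columns \code{lon}, \code{lat}, a
#'   list of such data.frames (land = inside any), or NULL / an empty
#'   data.frame for all-water
#' @return a \linkS4class{LandMask}
#' @export
generateGulfMask <- function(latRange = c(15, 32), lonRange = c(-100, -75),
                             resolutionKm = 32,
                             coastPolygon = gulfCoastPolygon()) {
  coords <- gridCoords(latRange, lonRange, resolutionKm)
  polys <- .asPolygonList(coastPolygon)
  nlat <- length(coords$lats)
  nlon <- length(coords$lons)
  cellLon <- rep(coords$lons, each = nlat)
  cellLat <- rep(coords$lats, times = nlon)
  land <- rep(FALSE, nlat * nlon)
  for (p in polys) {
    if (nrow(p) == 0) next
    land <- land | pracma::inpolygon(cellLon, cellLat, p$lon, p$lat,
      boundary = TRUE)
  }
  landMask(coords$lats, coords$lons, matrix(land, nlat, nlon))
}

#' Has a position reached land?
#'
#' TRUE iff at least one of the four raster nodes nearest the query position
#' (by great-circle distance) is land. Positions outside the raster's
#' node extent raise a domain-exit condition, which the trajectory module
#' records as termination reason \code{"domain_exit"}.
#'
#' @param mask a \linkS4class{LandMask}
#' @param lat,lon query position, degrees
#' @return logical
#' @export
reachedLand <- function(mask, lat, lon) {
  if (lat < mask@lats[1] || lat > mask@lats[length(mask@lats)] ||
      lon < mask@lons[1] || lon > mask@lons[length(mask@lons)]) {
    .extentError("position outside land-mask extent")
  }
  # candidate nodes: a small index window around the query (grid is
  # regular, so the 4 nearest nodes are always inside it)
  ilat <- findInterval(lat, mask@lats)
  ilon <- findInterval(lon, mask@lons)
  li <- max(1L, ilat - 1L):min(length(mask@lats), ilat + 2L)
  lj <- max(1L, ilon - 1L):min(length(mask@lons), ilon + 2L)
  cand <- expand.grid(i = li, j = lj)
  d <- geosphere::distHaversine(cbind(lon, lat),
    cbind(mask@lons[cand$j], mask@lats[cand$i]), r = EARTH_RADIUS_M)
  nearest <- cand[order(d)[1:4], ]
  any(mask@isLand[cbind(nearest$i, nearest$j)])
}
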