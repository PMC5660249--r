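setOldClass(c("POSIXct", "POSIXt"))
setOldClass("Date")

#' WindGrid: a gridded u/v wind field
#'
#' Regular space-time grid of eastward (u) and northward (v) wind components,
#' emulating a regional reanalysis product (3-hourly snapshots, ~32-km
#' horizontal spacing, a single altitude level). Arrays are indexed
#' \code{[time, lat, lon]}.
#'
#' @slot lats numeric, degrees north, strictly ascending with constant step.
#' @slot lons numeric, degrees east, strictly ascending with constant step.
#' @slot times POSIXct (UTC), strictly increasing with a constant 3-h step.
#' @slot u,v numeric arrays \code{[time, lat, lon]}, m/s, all finite.
#' @slot meta list of free-form metadata (grid spacing km, altitude label).
#'
#' @exportClass WindGrid
setClass("WindGrid",
  representation(
    lats = "numeric", lons = "numeric", times = "POSIXct",
    u = "array", v = "array", meta = "list"
  )
)

.checkRegular <- function(x, what, tol = 1e-8) {
  if (length(x) < 2) return(NULL)
  d <- diff(x)
  if (any(d <= 0)) return(sprintf("%s must be strictly increasing", what))
  if (max(d) - min(d) > tol * max(abs(d))) {
    return(sprintf("%s must have a constant step", what))
  }
  NULL
}

setValidity("WindGrid", function(object) {
  msgs <- character()
  msgs <- c(msgs, .checkRegular(object@lats, "lats"))
  msgs <- c(msgs, .checkRegular(object@lons, "lons"))
  msgs <- c(msgs, .checkRegular(as.numeric(object@times), "times"))
  if (length(object@times) >= 2) {
    step <- diff(as.numeric(object@times))[1]
    if (abs(step - 3 * 3600) > 1e-6) {
      msgs <- c(msgs, "times must be spaced exactly 3 hours apart")
    }
  }
  dims <- c(length(object@times), length(object@lats), length(object@lons))
  if (!identical(dim(object@u), dims) || !identical(dim(object@v), dims)) {
    msgs <- c(msgs, "u and v must be arrays of dim [time, lat, lon]")
  } else if (!all(is.finite(object@u)) || !all(is.finite(object@v))) {
    msgs <- c(msgs, "u and v must be finite everywhere")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn WindGrid constructor
#' @param lats,lons,times,u,v,meta see slots
#' @export
windGrid <- function(lats, lons, times, u, v, meta = list()) {
  new("WindGrid",
    lats = as.numeric(lats), lons = as.numeric(lons),
    times = as.POSIXct(times, tz = "UTC"),
    u = u, v = v, meta = meta
  )
}

setMethod("show", "WindGrid", function(object) {
  cat("WindGrid:", length(object@times), "times x",
    length(object@lats), "lats x", length(object@lons), "lons\n")
  cat("  lat:", min(object@lats), "to", max(object@lats),
    " lon:", min(object@lons), "to", max(object@lons), "\n")
  cat("  time:", format(min(object@times), "%Y-%m-%d %H:%M", tz = "UTC"),
    "to", format(max(object@times), "%Y-%m-%d %H:%M", tz = "UTC"), "UTC\n")
  if (length(object@meta)) {
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
      sep = "=", collapse = ", "), "\n")
  }
})

#' @rdname WindGrid-accessors
#' @param x a \code{WindGrid} or \code{LandMask}
#' @export
setGeneric("lats", function(x) standardGeneric("lats"))
#' @rdname WindGrid-accessors
#' @export
setGeneric("lons", function(x) standardGeneric("lons"))
#' @rdname WindGrid-accessors
#' @export
setGeneric("timesUTC", function(x) standardGeneric("timesUTC"))
#' @rdname WindGrid-accessors
#' @export
setGeneric("uwind", function(x) standardGeneric("uwind"))
#' @rdname WindGrid-accessors
#' @export
setGeneric("vwind", function(x) standardGeneric("vwind"))

#' Accessors for WindGrid and LandMask
#' @name WindGrid-accessors
#' @param x a \code{WindGrid} or \code{LandMask}
NULL

#' @rdname WindGrid-accessors
setMethod("lats", "WindGrid", function(x) x@lats)
#' @rdname WindGrid-accessors
setMethod("lons", "WindGrid", function(x) x@lons)
#' @rdname WindGrid-accessors
setMethod("timesUTC", "WindGrid", function(x) x@times)
#' @rdname WindGrid-accessors
setMethod("uwind", "WindGrid", function(x) x@u)
#' @rdname WindGrid-accessors
setMethod("vwind", "WindGrid", function(x) x@v)

#' LandMask: a boolean land/water raster
#'
#' Regular raster of land/water cells on the same coordinate conventions as
#' \linkS4class{WindGrid} (ascending cell-center coordinates). A modelled
#' migrant "reaches land" when at least one of the four raster nodes nearest
#' its position is land.
#'
#' @slot lats,lons numeric cell-center coordinates, ascending, constant step.
#' @slot isLand logical matrix \code{[lat, lon]}.
#'
#' @exportClass LandMask
setClass("LandMask",
  representation(lats = "numeric", lons = "numeric", isLand = "matrix")
)

setValidity("LandMask", function(object) {
  msgs <- character()
  msgs <- c(msgs, .checkRegular(object@lats, "lats"))
  msgs <- c(msgs, .checkRegular(object@lons, "lons"))
  if (!is.logical(object@isLand)) msgs <- c(msgs, "isLand must be logical")
  if (!identical(dim(object@isLand),
    c(length(object@lats), length(object@lons)))) {
    msgs <- c(msgs, "isLand must be a [lat, lon] matrix")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn LandMask constructor
#' @param lats,lons,isLand see slots
#' @export
landMask <- function(lats, lons, isLand) {
  new("LandMask", lats = as.numeric(lats), lons = as.numeric(lons),
    isLand = isLand)
}

setMethod("show", "LandMask", function(object) {
  cat("LandMask:", length(object@lats), "x", length(object@lons), "cells;",
    sum(object@isLand), "land,", sum(!object@isLand), "water\n")
})

#' @rdname WindGrid-accessors
setMethod("lats", "LandMask", function(x) x@lats)
#' @rdname WindGrid-accessors
setMethod("lons", "LandMask", function(x) x@lons)

#' @rdname WindGrid-accessors
#' @export
setGeneric("isLand", function(x) standardGeneric("isLand"))
#' @rdname WindGrid-accessors
setMethod("isLand", "LandMask", function(x) x@isLand)

#' Track: one simulated trans-Gulf trajectory
#'
#' A single forward-simulated flight: constant heading (solved from the wind
#' at departure), constant airspeed, hourly loxodrome steps under
#' interpolated winds. Point \code{i} records the state at the start of the
#' \code{i}-th one-hour step; the landing/exit position reached after the
#' final step is kept in \code{endPosition}.
#'
#' @slot departureDir intended track direction at departure, degrees toward.
#' @slot heading constant body-axis orientation, degrees.
#' @slot airspeed constant airspeed, m/s.
#' @slot points data.frame with one row per step: \code{time, lat, lon, u, v,
#'   windSpeed, windDir, groundspeed, trackDir, tailwind} (tailwind w.r.t.
#'   \code{departureDir}).
#' @slot termination one of \code{"reached_land"}, \code{"max_steps"},
#'   \code{"domain_exit"}.
#' @slot meanTailwind arithmetic mean of the per-step tailwinds.
#' @slot endPosition named numeric \code{c(lat, lon)} after the last advance.
#'
#' @exportClass Track
setClass("Track",
  representation(
    departureDir = "numeric", heading = "numeric", airspeed = "numeric",
    points = "data.frame", termination = "character",
    meanTailwind = "numeric", endPosition = "numeric"
  )
)

setValidity("Track", function(object) {
  msgs <- character()
  if (nrow(object@points) < 1) msgs <- c(msgs, "points must be nonempty")
  if (!object@termination %in% c("reached_land", "max_steps", "domain_exit")) {
    msgs <- c(msgs, "unknown termination reason")
  }
  if (nrow(object@points) &&
      abs(object@meanTailwind - mean(object@points$tailwind)) > 1e-9) {
    msgs <- c(msgs, "meanTailwind must equal the mean of point tailwinds")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Track", function(object) {
  cat(sprintf(
    "Track toward %g deg (heading %.2f deg): %d steps, %s, mean tailwind %.2f m/s\n",
    object@departureDir, object@heading, nrow(object@points),
    object@termination, object@meanTailwind))
})

#' @rdname Track-accessors
#' @param x a \code{Track}
#' @export
setGeneric("trackPoints", function(x) standardGeneric("trackPoints"))
#' @rdname Track-accessors
#' @export
setGeneric("termination", function(x) standardGeneric("termination"))
#' @rdname Track-accessors
#' @export
setGeneric("meanTailwind", function(x) standardGeneric("meanTailwind"))

#' Accessors for Track
#' @name Track-accessors
#' @param x a \code{Track}
NULL

#' @rdname Track-accessors
setMethod("trackPoints", "Track", function(x) x@points)
#' @rdname Track-accessors
setMethod("termination", "Track", function(x) x@termination)
#' @rdname Track-accessors
setMethod("meanTailwind", "Track", function(x) x@meanTailwind)

#' NightSim: the five simulated tracks of one night
#'
#' Result of launching the five departure-direction tracks from the origin at
#' civil twilight of one night.
#'
#' @slot date the night's local evening date.
#' @slot twilight POSIXct (UTC) launch instant.
#' @slot tracks list of \linkS4class{Track} (one per feasible departure
#'   direction; infeasible headings are dropped and counted).
#' @slot gulfMeanTailwind mean over tracks of the per-track mean tailwind.
#' @slot departureTailwind mean over tracks of the first-step tailwind.
#' @slot valid TRUE iff all five tracks were feasible.
#'
#' @exportClass NightSim
setClass("NightSim",
  representation(
    date = "Date", twilight = "POSIXct", tracks = "list",
    gulfMeanTailwind = "numeric", departureTailwind = "numeric",
    valid = "logical"
  )
)

setMethod("show", "NightSim", function(object) {
  cat(sprintf(
    "NightSim %s: %d tracks, departure tailwind %.2f, gulf mean %.2f m/s%s\n",
    format(object@date), length(object@tracks), object@departureTailwind,
    object@gulfMeanTailwind, if (object@valid) "" else " [invalid]"))
})

#' MCResult: a one-tailed Monte-Carlo randomization test
#'
#' Observed statistic, the resampled null distribution, and the one-tailed
#' p-value computed as (r + 1) / (nSims + 1), where r counts resampled draws
#' at least as extreme as the observed statistic. The tail is chosen by the
#' sign of (observed - mean of the resampled draws); draws exactly equal to
#' the observed statistic count toward r.
#'
#' @slot observed observed statistic.
#' @slot draws numeric vector of resampled statistics (length nSims).
#' @slot expectedMean mean of \code{draws}.
#' @slot r integer count of draws at least as extreme as observed.
#' @slot p one-tailed p-value, in [1/(nSims+1), 1].
#' @slot side \code{"greater"} or \code{"less"}.
#' @slot seed integer seed used (NA if none supplied).
#'
#' @exportClass MCResult
setClass("MCResult",
  representation(
    observed = "numeric", draws = "numeric", expectedMean = "numeric",
    r = "integer", p = "numeric", side = "character", seed = "integer"
  )
)

setValidity("MCResult", function(object) {
  n <- length(object@draws)
  if (n < 1) return("draws must be nonempty")
  lo <- 1 / (n + 1)
  if (object@p < lo - 1e-12 || object@p > 1 + 1e-12) {
    return("p must lie in [1/(nSims+1), 1]")
  }
  TRUE
})

setMethod("show", "MCResult", function(object) {
  cat(sprintf(
    "MCResult: observed %.4f vs expected %.4f (%d sims, side %s), p = %.4g\n",
    object@observed, object@expectedMean, length(object@draws), object@side,
    object@p))
})

#' @rdname MCResult-accessors
#' @param x an \code{MCResult}
#' @export
setGeneric("observedStat", function(x) standardGeneric("observedStat"))
#' @rdname MCResult-accessors
#' @export
setGeneric("expectedDraws", function(x) standardGeneric("expectedDraws"))
#' @rdname MCResult-accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' Accessors for MCResult
#' @name MCResult-accessors
#' @param x an \code{MCResult}
NULL

#' @rdname MCResult-accessors
setMethod("observedStat", "MCResult", function(x) x@observed)
#' @rdname MCResult-accessors
setMethod("expectedDraws", "MCResult", function(x) x@draws)
#' @rdname MCResult-accessors
setMethod("pValue", "MCResult", function(x) x@p)

#' SelectivityFit: a logistic selectivity model
#'
#' Logistic regression of a binary arrival/departure decision on period
#' (early/late season), tailwind, and their interaction, with per-term Wald
#' z-tests, the model-vs-null chi-square test, and variance inflation
#' factors computed from the design matrix.
#'
#' @slot coefTable matrix with columns Estimate, SE, z, p (one row per term).
#' @slot nullDeviance,residDeviance deviances of the intercept-only and
#'   fitted models.
#' @slot chisq,df,p model-vs-null likelihood-ratio test.
#' @slot vif named numeric, one VIF per non-intercept design column.
#' @slot fit the underlying \code{glm} object.
#'
#' @exportClass SelectivityFit
setClass("SelectivityFit",
  representation(
    coefTable = "matrix", nullDeviance = "numeric", residDeviance = "numeric",
    chisq = "numeric", df = "numeric", p = "numeric", vif = "numeric",
    fit = "ANY"
  )
)

setValidity("SelectivityFit", function(object) {
  msgs <- character()
  if (object@residDeviance > object@nullDeviance + 1e-8) {
    msgs <- c(msgs, "residual deviance cannot exceed null deviance")
  }
  if (length(object@vif) && any(object@vif < 1 - 1e-8)) {
    msgs <- c(msgs, "VIFs must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SelectivityFit", function(object) {
  cat("SelectivityFit (logistic):\n")
  print(round(object@coefTable, 4))
  cat(sprintf("model vs null: chisq = %.3f, df = %d, p = %.4g\n",
    object@chisq, as.integer(object@df), object@p))
  cat("VIF:", paste(names(object@vif), round(object@vif, 2), sep = "=",
    collapse = ", "), "\n")
})

#' @rdname SelectivityFit-accessors
#' @param x a \code{SelectivityFit}
#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))
#' @rdname SelectivityFit-accessors
#' @export
setGeneric("vifValues", function(x) standardGeneric("vifValues"))
#' @rdname SelectivityFit-accessors
#' @export
setGeneric("modelChisq", function(x) standardGeneric("modelChisq"))

#' Accessors for SelectivityFit
#' @name SelectivityFit-accessors
#' @param x a \code{SelectivityFit}
NULL

#' @rdname SelectivityFit-accessors
setMethod("coefTable", "SelectivityFit", function(x) x@coefTable)
#' @rdname SelectivityFit-accessors
setMethod("vifValues", "SelectivityFit", function(x) x@vif)
#' @rdname SelectivityFit-accessors
setMethod("modelChisq", "SelectivityFit", function(x)
  c(chisq = x@chisq, df = x@df, p = x@p))
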