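# Synthetic bird-night records: nightly tailwinds from a wind grid, a
# median-date period split, and binary stopover/departure flags drawn from
# a logistic dependence on tailwind.

#' Configuration for the synthetic bird-night generator
#'
#' The stopover flag of each night is drawn from a Bernoulli with
#' probability \code{plogis(beta0 + betaTailwind * tw + betaPeriod * late +
#' betaInteraction * late * tw)}, where \code{tw} is the night-mean tailwind
#' and \code{late} is 1 for nights on or after the median date. The
#' departure flag uses the same model structure with its own coefficients
#' and the civil-twilight tailwind as predictor. Default coefficient
#' magnitudes mirror the fitted arrival and departure selectivity models of
#' the study system.
#'
#' @param beta0,betaTailwind,betaPeriod,betaInteraction stopover-model
#'   logistic coefficients
#' @param depBeta0,depBetaTailwind,depBetaPeriod,depBetaInteraction
#'   departure-model logistic coefficients
#' @param nNights optional cap on the number of nights generated
#' @param closureProb probability that the banding station is closed the
#'   following morning (such nights get \code{available = 0} and are
#'   excluded from the analyses); default matches the study's closure rate
#'   of 78 closed days over 1281 station-nights
#' @param seed integer seed
#' @return a validated config (list of class \code{birdSimConfig})
#' @export
birdSimConfig <- function(beta0 = -0.22, betaTailwind = 0.17,
                          betaPeriod = 0.168, betaInteraction = -0.128,
                          depBeta0 = -0.375, depBetaTailwind = 0.023,
                          depBetaPeriod = -0.658, depBetaInteraction = 0.014,
                          nNights = NULL, closureProb = 78 / 1281,
                          seed = NULL) {
  if (!is.null(nNights) && nNights < 1) stop("nNights must be >= 1")
  stopifnot(closureProb >= 0, closureProb < 1)
  structure(list(
    beta0 = beta0, betaTailwind = betaTailwind, betaPeriod = betaPeriod,
    betaInteraction = betaInteraction,
    depBeta0 = depBeta0, depBetaTailwind = depBetaTailwind,
    depBetaPeriod = depBetaPeriod, depBetaInteraction = depBetaInteraction,
    nNights = nNights, closureProb = closureProb, seed = seed
  ), class = "birdSimConfig")
}

#' Draw binary night flags from the logistic selectivity model
#'
#' Vectorized core of the bird-night generator: given per-night tailwinds
#' and period indicators, draws Bernoulli flags with logistic probability
#' \code{plogis(b0 + bt * tw + bp * late + bi * late * tw)}.
#'
#' @param tw numeric tailwinds, m/s
#' @param late 0/1 period indicator (1 = late season)
#' @param b0,bt,bp,bi logistic coefficients
#' @return integer 0/1 vector
#' @export
drawNightFlags <- function(tw, late, b0, bt, bp = 0, bi = 0) {
  p <- plogis(b0 + bt * tw + bp * late + bi * late * tw)
  rbinom(length(tw), 1, p)
}

#' Generate synthetic bird-night records
#'
#' Produces one record per night covered by the wind grid: the night-mean
#' and twilight tailwinds at the site (via \code{\link{nightlySummary}}),
#' the early/late period assignment (median-date split), availability
#' (station open the following morning), and stopover/departure flags drawn
#' from the logistic selectivity model in \code{config}. Nights whose wind
#' samples fall outside the grid raise an error if explicitly requested,
#' and are otherwise not generated.
#'
#' @param grid a \linkS4class{WindGrid}
#' @param site \code{c(lat, lon)}
#' @param config a \code{\link{birdSimConfig}}
#' @param dates optional vector of night (evening) dates; defaults to every
#'   night whose five UTC samples the grid covers
#' @param referenceDirs reference directions for the tailwind summaries
#' @return data.frame with columns \code{date, year, period, stopover,
#'   departure, available, tailwind_night_mean, tailwind_twilight}
#' @export
generateBirdNights <- function(grid, site, config,
                               dates = NULL,
                               referenceDirs = c(120, 150, 180, 210, 240)) {
  stopifnot(inherits(config, "birdSimConfig"))
  explicitDates <- !is.null(dates)
  if (is.null(dates)) {
    # night D: twilight on evening D, samples at D+1 00:00..12:00 UTC
    dayRange <- as.Date(range(grid@times))
    dates <- seq(dayRange[1], dayRange[2] - 1, by = "day")
  }
  dates <- as.Date(dates)
  summaries <- lapply(dates, function(d) {
    nightlySummary(grid, site, d, referenceDirs = referenceDirs)
  })
  ok <- !vapply(summaries, `[[`, logical(1), "missing")
  if (explicitDates && !all(ok)) {
    stop("requested night(s) outside the wind grid's time range: ",
      paste(format(dates[!ok]), collapse = ", "))
  }
  dates <- dates[ok]
  summaries <- summaries[ok]
  if (!is.null(config$nNights)) {
    keep <- seq_len(min(config$nNights, length(dates)))
    dates <- dates[keep]
    summaries <- summaries[keep]
  }
  if (!length(dates)) stop("no nights covered by the wind grid")
  tw <- vapply(summaries, `[[`, numeric(1), "meanTailwind")
  twi <- vapply(summaries, `[[`, numeric(1), "twilightTailwind")
  split <- stats::median(dates)
  late <- as.integer(!(dates < split))
  if (!is.null(config$seed)) set.seed(config$seed)
  stopover <- drawNightFlags(tw, late, config$beta0, config$betaTailwind,
    config$betaPeriod, config$betaInteraction)
  departure <- drawNightFlags(twi, late, config$depBeta0,
    config$depBetaTailwind, config$depBetaPeriod, config$depBetaInteraction)
  available <- 1L - rbinom(length(dates), 1, config$closureProb)
  data.frame(
    date = dates,
    year = as.integer(format(dates, "%Y")),
    period = ifelse(late == 1L, "late", "early"),
    stopover = stopover,
    departure = departure,
    available = available,
    tailwind_night_mean = tw,
    tailwind_twilight = twi
  )
}
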