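# Forecasting-consistency metrics: do departure-time winds predict the
# winds a migrant meets over the Gulf?

#' Supportiveness consistency of one track
#'
#' Classifies every step of a track as supportive (tailwind > 0) or not and
#' compares each step against the first step:
#' \itemize{
#'   \item \code{proportionConsistent}: fraction of steps whose
#'     supportiveness matches the first step's;
#'   \item \code{hoursToChange}: length (in whole one-hour steps) of the
#'     initial run matching the first step, i.e. the first differing step
#'     minus one; \code{NA} when the whole track is consistent;
#'   \item \code{consistentWhole}: TRUE iff no step differs.
#' }
#' The three fields are linked: \code{consistentWhole} iff
#' \code{proportionConsistent == 1} iff \code{hoursToChange} is \code{NA}.
#'
#' @param track a \linkS4class{Track}, or a numeric vector of per-step
#'   tailwinds
#' @return list with \code{consistentWhole}, \code{proportionConsistent},
#'   \code{hoursToChange}
#' @export
trackConsistency <- function(track) {
  tw <- if (is(track, "Track")) track@points$tailwind else as.numeric(track)
  if (!length(tw)) stop("track must be nonempty")
  s <- isSupportive(tw)
  match <- s == s[1]
  firstChange <- which(!match)[1]
  list(
    consistentWhole = all(match),
    proportionConsistent = mean(match),
    hoursToChange = if (all(match)) NA_integer_ else
      as.integer(firstChange - 1L)
  )
}

#' Night-level consistency summaries
#'
#' Aggregates \code{\link{trackConsistency}} across the (typically five)
#' tracks of a night. Cross-track aggregation can be read two ways, so both
#' are exposed: \code{meanProportion} (arithmetic mean of the per-track
#' proportions; the headline night-level metric) and
#' \code{fractionConsistent} (fraction of tracks consistent for the whole
#' crossing).
#'
#' @param night a \linkS4class{NightSim}
#' @return list with \code{meanProportion}, \code{fractionConsistent},
#'   \code{anyConsistent}, \code{allConsistent}
#' @export
nightConsistency <- function(night) {
  cs <- lapply(night@tracks, trackConsistency)
  props <- vapply(cs, `[[`, numeric(1), "proportionConsistent")
  whole <- vapply(cs, `[[`, logical(1), "consistentWhole")
  list(
    meanProportion = mean(props),
    fractionConsistent = mean(whole),
    anyConsistent = any(whole),
    allConsistent = all(whole)
  )
}

#' Relation between departure-time and Gulf-wide tailwinds
#'
#' Pearson correlation (with its t-based p-value) between the tailwind at
#' the origin at departure and the mean tailwind over the simulated
#' crossing, plus the paired mean difference (gulf - departure) and its SD.
#'
#' @param departureTailwind,gulfTailwind paired per-night tailwinds, m/s
#'   (>= 3 nights, non-constant)
#' @return list with \code{r}, \code{df}, \code{p}, \code{meanDiff},
#'   \code{sdDiff}
#' @export
departureGulfRelation <- function(departureTailwind, gulfTailwind) {
  ok <- complete.cases(departureTailwind, gulfTailwind)
  x <- departureTailwind[ok]
  y <- gulfTailwind[ok]
  if (length(x) < 3) stop("need at least 3 nights with both metrics")
  if (var(x) == 0 || var(y) == 0) stop("zero variance in tailwinds")
  ct <- cor.test(x, y, method = "pearson")
  list(
    r = unname(ct$estimate), df = unname(ct$parameter),
    p = ct$p.value,
    meanDiff = mean(y - x), sdDiff = sd(y - x)
  )
}

#' The three forecasting Monte-Carlo tests
#'
#' Tests whether migrants departed on nights when (1) Gulf-wide tailwinds,
#' (2) the improvement from departure to Gulf winds (gulf - departure), and
#' (3) the mean proportion of track steps consistent with departure
#' supportiveness were better than expected from random night selection.
#' Each is a \code{\link{mcMeanTest}} with the departure nights as the
#' selected set; the tests reuse the same night-selection machinery as the
#' selectivity module. Sub-seeds \code{seed}, \code{seed + 1},
#' \code{seed + 2} drive the three tests.
#'
#' @param nights data.frame with per-night columns \code{gulf},
#'   \code{departure} (tailwinds, m/s) and \code{consistency} (mean
#'   proportion consistent)
#' @param departed logical (or 0/1) vector marking departure nights
#' @param nSims,seed as in \code{\link{mcMeanTest}}
#' @return named list of three \linkS4class{MCResult}: \code{gulf},
#'   \code{difference}, \code{consistency}
#' @export
forecastingMCSuite <- function(nights, departed, nSims = 1000, seed = NULL) {
  departed <- as.logical(departed)
  stopifnot(length(departed) == nrow(nights))
  k <- sum(departed)
  if (k < 1) stop("no departure nights")
  vals <- list(
    gulf = nights$gulf,
    difference = nights$gulf - nights$departure,
    consistency = nights$consistency
  )
  res <- list()
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    res[[names(vals)[i]]] <- mcMeanTest(
      v, k, mean(v[departed]), nSims = nSims,
      seed = if (is.null(seed)) NULL else seed + i - 1
    )
  }
  res
}
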