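# Arrival/departure selectivity statistics: the period split, logistic
# selectivity models with VIFs, the full-sample and windowed Monte-Carlo
# randomization tests, and the annual capture-rate regression.

#' Assign early/late period by the median capture date
#'
#' Splits the season at the median capture date (computed from captured
#' birds, not from all nights): nights strictly before the split are
#' "early", the split date itself and later nights are "late" -- matching
#' the dummy coding early = 0, late = 1 used by the selectivity models.
#'
#' @param records night-record data.frame with a \code{date} column
#' @param splitDate optional explicit split date
#' @param captureDates optional capture dates used to compute the median;
#'   when omitted, dates of nights with \code{stopover == 1} are used
#' @return \code{records} with its \code{period} column (re)set
#' @export
assignPeriod <- function(records, splitDate = NULL, captureDates = NULL) {
  if (is.null(splitDate)) {
    if (is.null(captureDates)) {
      if (!"stopover" %in% names(records)) {
        stop("supply splitDate or captureDates, or records with a stopover flag")
      }
      captureDates <- records$date[records$stopover == 1]
    }
    if (!length(captureDates)) {
      stop("no captures available to compute the median split date")
    }
    splitDate <- stats::median(as.Date(captureDates))
  }
  records$period <- ifelse(as.Date(records$date) < as.Date(splitDate),
    "early", "late")
  records
}

#' Fit a logistic selectivity model
#'
#' Logistic regression (maximum likelihood via IRLS, \code{stats::glm}) of a
#' binary decision on period, tailwind, and their interaction:
#' \code{response ~ period + tailwind + period:tailwind}, with period dummy
#' coded early = 0, late = 1. Nights with \code{available == 0} or missing
#' tailwind are dropped first. Reports per-term Wald z-tests, the
#' model-vs-null chi-square (null deviance minus residual deviance on the
#' difference in degrees of freedom), and variance inflation factors
#' computed by regressing each design-matrix column on the others
#' (VIF = 1 / (1 - R^2)).
#'
#' @param records night-record data.frame (see
#'   \code{\link{generateBirdNights}})
#' @param response \code{"stopover"} or \code{"departure"}
#' @param predictor which tailwind drives the decision:
#'   \code{"night_mean"} (arrival models) or \code{"twilight"} (departure
#'   models)
#' @param includeYear add year as a covariate (the headline models use
#'   period and tailwind only)
#' @return a \linkS4class{SelectivityFit}; perfect separation aborts with a
#'   condition of class \code{gulfcross_separation_error}
#' @export
fitSelectivityGLM <- function(records,
                              response = c("stopover", "departure"),
                              predictor = c("night_mean", "twilight"),
                              includeYear = FALSE) {
  response <- match.arg(response)
  predictor <- match.arg(predictor)
  twcol <- if (predictor == "night_mean") "tailwind_night_mean" else
    "tailwind_twilight"
  d <- records
  if ("available" %in% names(d)) d <- d[d$available == 1, ]
  d <- d[!is.na(d[[twcol]]) & !is.na(d[[response]]), ]
  y <- d[[response]]
  if (length(unique(y)) < 2) {
    stop("need both response classes among available nights")
  }
  dat <- data.frame(
    y = y,
    period = factor(d$period, levels = c("early", "late")),
    tailwind = d[[twcol]]
  )
  form <- y ~ period * tailwind
  if (includeYear) {
    dat$year <- d$year
    form <- y ~ period * tailwind + year
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, data = dat, family = binomial("logit")),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated || !fit$converged || any(abs(coef(fit)) > 1e3, na.rm = TRUE)) {
    stop(structure(
      class = c("gulfcross_separation_error", "error", "condition"),
      list(message = "perfect separation detected; fit aborted",
        call = sys.call())
    ))
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  ct <- cbind(Estimate = est, SE = se, z = z, p = 2 * pnorm(-abs(z)))
  chisq <- fit$null.deviance - fit$deviance
  df <- fit$df.null - fit$df.residual
  new("SelectivityFit",
    coefTable = ct,
    nullDeviance = fit$null.deviance, residDeviance = fit$deviance,
    chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE),
    vif = designVIF(model.matrix(fit)),
    fit = fit
  )
}

#' Variance inflation factors of a design matrix
#'
#' For each non-intercept column, the R-squared of its least-squares
#' regression on all other columns (plus an intercept) gives
#' VIF = 1 / (1 - R^2). Orthogonal balanced designs give VIF = 1 exactly.
#'
#' @param X design matrix (an intercept column, if present, is dropped)
#' @return named numeric vector of VIFs
#' @export
designVIF <- function(X) {
  keep <- apply(X, 2, function(col) var(col) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) return(numeric(0))
  if (ncol(X) == 1) return(setNames(1, colnames(X)))
  R <- cor(X)
  vif <- diag(solve(R))
  setNames(pmax(vif, 1), colnames(X))
}

# Shared night-selection machinery: each simulation draws `k` of `n`
# available nights without replacement. Both mcMeanTest and windowMCTest
# consume the RNG stream identically, so the two agree exactly under the
# same seed when their designs coincide.
.mcDraws <- function(n, k, nSims) {
  lapply(seq_len(nSims), function(s) sample.int(n, k))
}

.mcFromDraws <- function(observed, draws, seed) {
  expectedMean <- mean(draws)
  side <- if (observed >= expectedMean) "greater" else "less"
  r <- if (side == "greater") sum(draws >= observed) else sum(draws <= observed)
  new("MCResult",
    observed = observed, draws = draws, expectedMean = expectedMean,
    r = as.integer(r), p = (r + 1) / (length(draws) + 1), side = side,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' Monte-Carlo test of a selected-night mean
#'
#' Tests whether the mean of a statistic over the selected nights (e.g.,
#' arrival or departure nights) differs from what random selection would
#' give: each of \code{nSims} draws samples \code{selectedCount} nights
#' without replacement from all available nights and records their mean.
#' The one-tailed p-value is (r + 1) / (nSims + 1), where r counts draws at
#' least as extreme as the observed mean, with the tail chosen by the sign
#' of (observed - mean of draw means); draws tied with the observed mean
#' count toward r.
#'
#' @param values per-night statistic over all available nights
#' @param selectedCount number of selected nights (> 0)
#' @param observedMean observed mean over the selected nights
#' @param nSims number of random draws
#' @param seed integer seed (results are deterministic given the seed)
#' @return an \linkS4class{MCResult}
#' @export
mcMeanTest <- function(values, selectedCount, observedMean, nSims = 1000,
                       seed = NULL) {
  if (selectedCount < 1) stop("selectedCount must be positive")
  if (selectedCount > length(values)) {
    stop("selectedCount exceeds the number of available nights")
  }
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(.mcDraws(length(values), selectedCount, nSims),
    function(idx) mean(values[idx]), numeric(1))
  .mcFromDraws(observedMean, draws, seed)
}

#' Windowed Monte-Carlo test around arrival nights
#'
#' For each offset k in \code{offsets} (nights relative to arrival), the
#' observed statistic is the mean tailwind over (focal arrival nights + k
#' days); the expected distribution redraws random "arrival nights" of the
#' same count from all available nights inside the focal window and applies
#' the same offset arithmetic. Only arrival nights inside the focal window
#' are used, so every offset night stays inside the recorded season and all
#' nights are equally represented. One draw of random nights serves all
#' offsets of a simulation (the window widens and shifts with the offset,
#' so the expected curve tracks seasonal changes in wind availability).
#'
#' @param records night-record data.frame with \code{date},
#'   \code{available}, a selection flag column and the value column
#' @param selection name of the 0/1 column marking the focal nights
#'   (default \code{"stopover"})
#' @param valueCol name of the per-night value column (default
#'   \code{"tailwind_night_mean"})
#' @param offsets integer night offsets (default -10..10)
#' @param focalWindow length-2 \code{Date}: only selected nights inside
#'   this window are focal (default 10 Sep - 21 Oct of each record year)
#' @param nSims,seed as in \code{\link{mcMeanTest}}
#' @return named list of \linkS4class{MCResult}, one per offset
#' @export
windowMCTest <- function(records, selection = "stopover",
                         valueCol = "tailwind_night_mean",
                         offsets = -10:10, focalWindow = NULL,
                         nSims = 1000, seed = NULL) {
  d <- records
  if ("available" %in% names(d)) d <- d[d$available == 1, ]
  d <- d[!is.na(d[[valueCol]]), ]
  d$date <- as.Date(d$date)
  inWindow <- if (is.null(focalWindow)) {
    md <- as.integer(format(d$date, "%m")) * 100 +
      as.integer(format(d$date, "%d"))
    md >= 910 & md <= 1021
  } else {
    d$date >= as.Date(focalWindow[1]) & d$date <= as.Date(focalWindow[2])
  }
  valueByDate <- setNames(d[[valueCol]], format(d$date))
  lookup <- function(dates) {
    v <- valueByDate[format(dates)]
    mean(v, na.rm = TRUE)
  }
  focal <- d$date[inWindow & d[[selection]] == 1]
  if (!length(focal)) stop("no focal selected nights inside the window")
  windowNights <- d$date[inWindow]
  m <- length(focal)
  if (!is.null(seed)) set.seed(seed)
  draws <- .mcDraws(length(windowNights), m, nSims)
  results <- list()
  for (k in offsets) {
    obs <- lookup(focal + k)
    sims <- vapply(draws, function(idx) lookup(windowNights[idx] + k),
      numeric(1))
    results[[as.character(k)]] <- .mcFromDraws(obs, sims, seed)
  }
  results
}

#' Annual capture-rate regression
#'
#' Ordinary least squares of annual capture rate (birds per net-hour) on
#' annual mean tailwind, with the overall F-test and adjusted R-squared --
#' the annual-scale selectivity check (more birds should stop over in years
#' with worse winds).
#'
#' @param captureRate annual capture rates (one per year, >= 3 years)
#' @param meanTailwind annual mean tailwinds, m/s
#' @return list with \code{slope}, \code{intercept}, \code{F}, \code{df},
#'   \code{adjR2}, \code{p}, and the underlying \code{lm} fit
#' @export
annualRegression <- function(captureRate, meanTailwind) {
  if (length(captureRate) < 3 || length(captureRate) != length(meanTailwind)) {
    stop("need matched annual series of at least 3 years")
  }
  if (var(meanTailwind) == 0) stop("constant predictor")
  fit <- lm(captureRate ~ meanTailwind)
  s <- summary(fit)
  list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    F = unname(s$fstatistic[1]),
    df = unname(s$fstatistic[2:3]),
    adjR2 = s$adj.r.squared,
    p = unname(pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
      lower.tail = FALSE)),
    fit = fit
  )
}
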