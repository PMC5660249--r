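# Period assignment, logistic selectivity models, Monte-Carlo mean tests,
# the windowed Monte-Carlo, and the annual regression.

mkRecords <- function(dates, tw, stopover, available = 1L) {
  data.frame(
    date = as.Date(dates), year = as.integer(format(as.Date(dates), "%Y")),
    period = NA_character_, stopover = stopover, departure = 0L,
    available = available, tailwind_night_mean = tw, tailwind_twilight = tw
  )
}

test_that("period splits at the median capture date, capture-based", {
  dates <- seq(as.Date("2010-09-01"), as.Date("2010-10-31"), by = "day")
  recs <- mkRecords(dates, rnorm(length(dates)), 0L)
  caps <- as.Date(c("2010-09-20", "2010-10-03", "2010-10-10"))
  out <- assignPeriod(recs, captureDates = caps)  # median 3 Oct
  expect_true(all(out$period[out$date < as.Date("2010-10-03")] == "early"))
  expect_true(all(out$period[out$date >= as.Date("2010-10-03")] == "late"))
  # duplicating every capture leaves the split unchanged
  out2 <- assignPeriod(recs, captureDates = rep(caps, each = 2))
  expect_identical(out$period, out2$period)
  # degenerate: all captures on one date; that date itself is "late"
  out3 <- assignPeriod(recs, captureDates = rep(as.Date("2010-10-01"), 5))
  expect_identical(out3$period[out3$date == as.Date("2010-10-01")], "late")
  expect_identical(out3$period[out3$date == as.Date("2010-09-30")], "early")
  expect_error(assignPeriod(recs, captureDates = as.Date(character())),
    "no captures")
})

test_that("the selectivity GLM recovers known generator coefficients", {
  set.seed(71)
  n <- 2000
  tw <- rnorm(n, 0, 3.6)
  late <- rep(0:1, each = n / 2)
  truth <- c(b0 = -0.22, bp = 0.168, bt = 0.17, bi = -0.128)
  y <- drawNightFlags(tw, late, truth["b0"], truth["bt"], truth["bp"],
    truth["bi"])
  recs <- mkRecords(seq(as.Date("2010-09-01"), by = "day", length.out = n),
    tw, y)
  recs$period <- ifelse(late == 1, "late", "early")
  fit <- fitSelectivityGLM(recs, "stopover", "night_mean")
  ct <- coefTable(fit)
  want <- c(truth["b0"], truth["bp"], truth["bt"], truth["bi"])
  expect_lt(max(abs(ct[, "Estimate"] - want) / ct[, "SE"]), 2)
  # model chi-square is null minus residual deviance
  expect_equal(unname(modelChisq(fit)["df"]), 3)
  expect_gt(unname(modelChisq(fit)["chisq"]), 0)
  # score identity: fitted probabilities average to the response rate
  expect_equal(mean(fitted(fit@fit)), mean(recs$stopover), tolerance = 1e-8)
})

test_that("VIFs come from the design matrix and are exact when orthogonal", {
  # orthogonal balanced factorial: all VIFs exactly 1
  X <- cbind(a = rep(c(-1, 1), each = 4), b = rep(c(-1, 1, -1, 1), 2),
    ab = rep(c(-1, 1), each = 4) * rep(c(-1, 1, -1, 1), 2))
  expect_identical(unname(designVIF(X)), c(1, 1, 1))
  # cross-check against car::vif on an interaction-free linear model
  set.seed(72)
  d <- data.frame(x1 = rnorm(300), x2 = rnorm(300), x3 = rnorm(300))
  d$x2 <- d$x2 + 0.6 * d$x1
  d$y <- rnorm(300)
  fit <- lm(y ~ x1 + x2 + x3, data = d)
  expect_equal(unname(designVIF(model.matrix(fit))),
    unname(car::vif(fit)), tolerance = 1e-6)
})

test_that("perfect separation aborts with a diagnostic condition", {
  n <- 200
  tw <- c(rnorm(n / 2, -8, 1), rnorm(n / 2, 8, 1))
  recs <- mkRecords(seq(as.Date("2010-09-01"), by = "day", length.out = n),
    tw, as.integer(tw > 0))
  recs$period <- rep(c("early", "late"), n / 2)
  expect_error(fitSelectivityGLM(recs, "stopover", "night_mean"),
    class = "gulfcross_separation_error")
})

test_that("mcMeanTest follows the (r+1)/(n+1) rule with ties as extreme", {
  # degenerate: identical values everywhere -> every draw ties -> p = 1
  res <- mcMeanTest(rep(3.5, 20), 6, 3.5, nSims = 500, seed = 1)
  expect_equal(pValue(res), 1)
  expect_identical(res@r, 500L)

  # exhaustive-subset oracle: nights {1..5}, select 2, observed {4,5}
  # mean 4.5; 1 of C(5,2) = 10 subset means is >= 4.5 -> exact p = 1/10
  vals <- 1:5
  exact <- mean(combn(5, 2, function(i) mean(vals[i])) >= 4.5)
  expect_equal(exact, 1 / 10)
  res2 <- mcMeanTest(vals, 2, 4.5, nSims = 10000, seed = 2)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(pValue(res2) - exact), 3 * se + 2e-4)
  expect_identical(res2@side, "greater")

  # observed at the population mean of symmetric values: p well above 0.4
  res3 <- mcMeanTest(c(-2, -1, 0, 1, 2), 3, 0, nSims = 4000, seed = 3)
  expect_gt(pValue(res3), 0.4)

  # p bounds and determinism
  expect_identical(pValue(mcMeanTest(rnorm(30), 5, 10, nSims = 200, seed = 4)),
    1 / 201)
  a <- mcMeanTest(sin(1:40), 7, 0.2, nSims = 300, seed = 9)
  b <- mcMeanTest(sin(1:40), 7, 0.2, nSims = 300, seed = 9)
  expect_identical(expectedDraws(a), expectedDraws(b))
  expect_identical(pValue(a), pValue(b))
  expect_error(mcMeanTest(1:5, 0, 1), "positive")
  expect_error(mcMeanTest(1:5, 9, 1), "exceeds")
})

test_that("windowMCTest at offset 0 over the full season equals mcMeanTest", {
  set.seed(73)
  dates <- seq(as.Date("2010-09-01"), as.Date("2010-10-31"), by = "day")
  tw <- rnorm(length(dates), 0, 3.6)
  stop <- rbinom(length(dates), 1, 0.4)
  stop[1] <- 1L
  recs <- mkRecords(dates, tw, stop)
  res <- windowMCTest(recs, offsets = 0,
    focalWindow = range(dates), nSims = 400, seed = 55)[["0"]]
  direct <- mcMeanTest(tw, sum(stop), mean(tw[stop == 1]), nSims = 400,
    seed = 55)
  expect_equal(expectedDraws(res), expectedDraws(direct), tolerance = 1e-12)
  expect_equal(pValue(res), pValue(direct))
  expect_identical(res@side, direct@side)
})

test_that("temporally constant wind makes every windowed contrast a tie", {
  dates <- seq(as.Date("2010-09-01"), as.Date("2010-10-31"), by = "day")
  set.seed(74)
  recs <- mkRecords(dates, rep(2.5, length(dates)),
    rbinom(length(dates), 1, 0.5))
  res <- windowMCTest(recs, offsets = -10:10, nSims = 100, seed = 8)
  expect_length(res, 21)
  for (r in res) {
    expect_equal(observedStat(r), 2.5)
    expect_equal(pValue(r), 1)
  }
})

test_that("offset windows shift with the focal nights", {
  # tailwind equal to the day-of-season index makes offset means analytic
  dates <- seq(as.Date("2010-09-01"), as.Date("2010-10-31"), by = "day")
  tw <- as.numeric(dates - dates[1])
  recs <- mkRecords(dates, tw, as.integer(dates %in% dates[c(20, 30, 40)]))
  res <- windowMCTest(recs, offsets = c(-3, 0, 5), nSims = 50, seed = 1)
  expect_equal(observedStat(res[["-3"]]), mean(c(19, 29, 39) - 3))
  expect_equal(observedStat(res[["0"]]), mean(c(19, 29, 39)))
  expect_equal(observedStat(res[["5"]]), mean(c(19, 29, 39) + 5))
})

test_that("annual regression recovers exact and noisy relationships", {
  tw <- c(-2, -1, 0, 1, 2, 3)
  y <- -0.001 * tw + 0.009
  res <- suppressWarnings(annualRegression(y, tw))  # exact fit warns
  expect_equal(res$slope, -0.001, tolerance = 1e-12)
  expect_equal(res$adjR2, 1, tolerance = 1e-9)

  set.seed(75)
  tw2 <- rnorm(21, 0, 1.5)
  y2 <- -0.001 * tw2 + 0.009 + rnorm(21, 0, 0.002)
  res2 <- annualRegression(y2, tw2)
  se <- summary(res2$fit)$coefficients[2, 2]
  expect_lt(abs(res2$slope - (-0.001)), 2 * se)

  expect_error(annualRegression(c(1, 2, 3), c(1, 1, 1)), "constant")
  expect_error(annualRegression(1:2, 1:2), "3 years")

  # permutation null: F-test p-values are uniform
  set.seed(76)
  ps <- replicate(300, {
    x <- rnorm(10)
    annualRegression(rnorm(10), x)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})
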