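# Wind-triangle heading, loxodrome stepping, landfall detection, and the
# full track / night simulations.

test_that("wind-triangle heading compensates crosswind exactly", {
  expect_equal(solveHeading(180, 0, 0, 10), 180)
  # pure tailwind: no crosswind, heading equals target
  expect_equal(solveHeading(180, 6, 180, 10), 180)
  # 5 m/s crosswind toward 90, airspeed 10: asin(1/2) = 30 deg correction
  h <- solveHeading(180, 5, 90, 10)
  expect_equal(h, 210)
  # the resulting ground vector points along the target
  gu <- 10 * sin(h * pi / 180) + 5
  gv <- 10 * cos(h * pi / 180) + 0
  expect_equal((atan2(gu, gv) * 180 / pi) %% 360, 180, tolerance = 1e-9)
  # randomized: realized track equals target whenever feasible
  set.seed(31)
  for (i in 1:100) {
    target <- runif(1, 0, 360)
    ws <- runif(1, 0, 9)
    wd <- runif(1, 0, 360)
    h <- solveHeading(target, ws, wd, 10)
    g <- uvToWind(10 * sin(h * pi / 180) + ws * sin(wd * pi / 180),
                  10 * cos(h * pi / 180) + ws * cos(wd * pi / 180))
    delta <- ((g$dirToward - target + 180) %% 360) - 180
    expect_lt(abs(delta), 1e-9)
  }
  expect_error(solveHeading(180, 12, 90, 10),
    class = "gulfcross_infeasible_heading")
})

test_that("a loxodrome step matches the rhumb destination formula", {
  # zero wind, due south, 1 h at 10 m/s: 36 km, longitude unchanged
  s <- trackStep(25, -90, 180, 10, 0, 0, 1)
  expect_equal(s$lat, 25 - 36 / (6371 * pi / 180), tolerance = 1e-9)
  expect_equal(s$lon, -90, tolerance = 1e-9)
  expect_equal(s$groundspeed, 10)

  # equal and opposite wind: the bird hovers
  s0 <- trackStep(25, -90, 90, 10, -10, 0, 1)
  expect_equal(s0$groundspeed, 0)
  expect_equal(c(s0$lat, s0$lon), c(25, -90))

  # ground vector is the air + wind vector sum, and the step lands on the
  # hand-rolled rhumb destination
  set.seed(32)
  for (i in 1:100) {
    h <- runif(1, 0, 360); a <- runif(1, 5, 15)
    u <- rnorm(1, sd = 5); v <- rnorm(1, sd = 5)
    la <- runif(1, 5, 45); lo <- runif(1, -100, -60)
    s <- trackStep(la, lo, h, a, u, v, 1)
    gu <- a * sin(h * pi / 180) + u
    gv <- a * cos(h * pi / 180) + v
    expect_equal(s$groundspeed, sqrt(gu^2 + gv^2), tolerance = 1e-9)
    want <- oracleRhumb(la, lo, (atan2(gu, gv) * 180 / pi) %% 360,
      sqrt(gu^2 + gv^2) * 3600)
    expect_equal(s$lat, want[["lat"]], tolerance = 1e-7)
    expect_equal(s$lon, want[["lon"]], tolerance = 1e-7)
  }
})

test_that("reaching land means >= 1 land node among the 4 nearest", {
  lats <- seq(20, 26, by = 1)
  lons <- seq(-90, -84, by = 1)
  land <- matrix(FALSE, length(lats), length(lons))
  m <- landMask(lats, lons, land)
  expect_false(reachedLand(m, 22.5, -87.5))
  land1 <- land
  land1[3, 3] <- TRUE  # node (22, -88)
  m1 <- landMask(lats, lons, land1)
  expect_true(reachedLand(m1, 22.4, -87.9))   # that node is among the 4
  expect_false(reachedLand(m1, 24.5, -85.5))  # far away
  expect_error(reachedLand(m1, 10, -87), class = "gulfcross_extent_error")

  # brute-force nearest-4 oracle on a random mask
  set.seed(33)
  landR <- matrix(runif(length(lats) * length(lons)) < 0.3,
    length(lats), length(lons))
  mr <- landMask(lats, lons, landR)
  nodes <- expand.grid(i = seq_along(lats), j = seq_along(lons))
  for (k in 1:200) {
    qla <- runif(1, 20, 26); qlo <- runif(1, -90, -84)
    d <- oracleDist(qla, qlo, lats[nodes$i], lons[nodes$j])
    near4 <- nodes[order(d)[1:4], ]
    expect_identical(reachedLand(mr, qla, qlo),
      any(landR[cbind(near4$i, near4$j)]))
  }
})

test_that("collinear uniform wind gives a straight supported track", {
  w <- 4
  g <- uniformGrid(0, -w, lats = c(0, 40), lons = c(-110, -60),
    nTimes = 50)  # toward 180
  cfg <- trajectoryConfig(origin = c(lat = 30.2, lon = -88))
  tr <- simulateTrack(g, waterMask(), cfg, 180, timesUTC(g)[1])
  pts <- trackPoints(tr)
  expect_equal(tr@heading, 180)
  expect_equal(unique(round(pts$groundspeed, 9)), 10 + w)
  expect_equal(meanTailwind(tr), w, tolerance = 1e-9)
  expect_identical(termination(tr), "max_steps")
  expect_identical(nrow(pts), 45L)
  expect_lt(max(abs(pts$lon - (-88))), 1e-9)
})

test_that("a track lands immediately when the mask sits beside the origin", {
  g <- uniformGrid(0, 0, lats = c(0, 40), lons = c(-110, -60), nTimes = 50)
  lats <- seq(29, 31, by = 0.25)
  lons <- seq(-89, -87, by = 0.25)
  land <- outer(lats < 30, rep(TRUE, length(lons)), FUN = "&")  # land south of 30
  m <- landMask(lats, lons, land)
  cfg <- trajectoryConfig(origin = c(lat = 30.2, lon = -88))
  tr <- simulateTrack(g, m, cfg, 180, timesUTC(g)[1])
  expect_identical(termination(tr), "reached_land")
  expect_identical(nrow(trackPoints(tr)), 1L)
})

test_that("uniform-wind tracks equal the closed-form rhumb advance", {
  set.seed(34)
  for (case in 1:5) {
    u0 <- rnorm(1, sd = 4); v0 <- rnorm(1, sd = 4)
    g <- uniformGrid(u0, v0, lats = c(-10, 45), lons = c(-130, -50),
      nTimes = 50)
    cfg <- trajectoryConfig(origin = c(lat = 30.2, lon = -88))
    dir <- sample(c(120, 150, 180, 210, 240), 1)
    tr <- simulateTrack(g, waterMask(lats = seq(-20, 50, 2),
      lons = seq(-140, -40, 2)), cfg, dir, timesUTC(g)[1])
    pts <- trackPoints(tr)
    expect_identical(nrow(pts), 45L)
    h <- tr@heading
    gu <- 10 * sin(h * pi / 180) + u0
    gv <- 10 * cos(h * pi / 180) + v0
    bearing <- (atan2(gu, gv) * 180 / pi) %% 360
    gs <- sqrt(gu^2 + gv^2)
    for (i in 2:45) {
      want <- oracleRhumb(30.2, -88, bearing, gs * 3600 * (i - 1))
      expect_lt(abs(pts$lat[i] - want[["lat"]]), 1e-6)
      expect_lt(abs(pts$lon[i] - want[["lon"]]), 1e-6)
    }
    # constant heading and airspeed, step conservation at every point
    expect_lt(max(abs(pts$groundspeed - gs)), 1e-9)
    expect_lt(max(abs(pts$tailwind -
      (u0 * sin(dir * pi / 180) + v0 * cos(dir * pi / 180)))), 1e-9)
  }
})

test_that("with zero wind all five tracks are 36 km/h rhumb lines", {
  g <- uniformGrid(0, 0, lats = c(-10, 45), lons = c(-130, -50), nTimes = 50)
  cfg <- trajectoryConfig(origin = c(lat = 30.2, lon = -88))
  ns <- simulateNight(g, waterMask(lats = seq(-20, 50, 2),
    lons = seq(-140, -40, 2)), cfg, as.Date("2010-09-02"))
  expect_true(ns@valid)
  expect_equal(ns@gulfMeanTailwind, 0)
  expect_equal(ns@departureTailwind, 0)
  for (tr in ns@tracks) {
    pts <- trackPoints(tr)
    expect_equal(tr@heading, tr@departureDir)
    expect_equal(unique(round(pts$groundspeed, 9)), 10)
    want <- oracleRhumb(30.2, -88, tr@departureDir, 36000 * 10)
    expect_lt(abs(pts$lat[11] - want[["lat"]]), 1e-6)
    expect_lt(abs(pts$lon[11] - want[["lon"]]), 1e-6)
  }
})

test_that("night summaries follow the cosine closed form in uniform wind", {
  # wind toward 180 at 4 m/s: departure tailwind = 4(2cos60 + 2cos30 + 1)/5
  g <- uniformGrid(0, -4, lats = c(-10, 45), lons = c(-130, -50), nTimes = 50)
  cfg <- trajectoryConfig(origin = c(lat = 30.2, lon = -88))
  ns <- simulateNight(g, waterMask(lats = seq(-20, 50, 2),
    lons = seq(-140, -40, 2)), cfg, as.Date("2010-09-02"))
  want <- 4 * (2 * cos(pi / 3) + 2 * cos(pi / 6) + 1) / 5
  expect_equal(ns@departureTailwind, want, tolerance = 1e-9)
  expect_equal(ns@gulfMeanTailwind, want, tolerance = 1e-9)
})

test_that("time-varying spatially-uniform wind matches a replay of stored tracks", {
  # wind varies by snapshot but not in space; replaying each stored step's
  # (u, v) against the departure direction must reproduce the gulf mean
  g <- functionGrid(function(t, la, lo) 2 * sin(t / 3),
                    function(t, la, lo) -3 - cos(t / 2),
                    lats = c(-10, 45), lons = c(-130, -50), nTimes = 50)
  cfg <- trajectoryConfig(origin = c(lat = 30.2, lon = -88))
  ns <- simulateNight(g, waterMask(lats = seq(-20, 50, 2),
    lons = seq(-140, -40, 2)), cfg, as.Date("2010-09-02"))
  replayMeans <- vapply(ns@tracks, function(tr) {
    pts <- trackPoints(tr)
    mean(pts$u * sin(tr@departureDir * pi / 180) +
         pts$v * cos(tr@departureDir * pi / 180))
  }, numeric(1))
  expect_equal(ns@gulfMeanTailwind, mean(replayMeans), tolerance = 1e-9)
  # per-step conservation: ground vector = air vector + wind vector
  for (tr in ns@tracks) {
    pts <- trackPoints(tr)
    gu <- tr@airspeed * sin(tr@heading * pi / 180) + pts$u
    gv <- tr@airspeed * cos(tr@heading * pi / 180) + pts$v
    expect_lt(max(abs(pts$groundspeed - sqrt(gu^2 + gv^2))), 1e-9)
  }
})

test_that("tracks terminate with a recorded reason and bounded length", {
  g <- studyGrid(nDays = 3, seed = 6)
  m <- studyMask()
  cfg <- trajectoryConfig()
  ns <- simulateNight(g, m, cfg, as.Date("2010-09-02"))
  for (tr in ns@tracks) {
    expect_lte(nrow(trackPoints(tr)), 45L)
    expect_true(termination(tr) %in%
      c("reached_land", "max_steps", "domain_exit"))
    expect_true(validObject(tr))
  }
})
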