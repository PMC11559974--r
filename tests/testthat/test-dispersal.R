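test_that("clipped normal sampling respects bounds and preserves the mean", {
  set.seed(1)
  ## degenerate normal
  expect_identical(sampleClippedNormal(0.6e-3, 0, 1, 1000),
                   rep(0.6e-3, 1000))
  ## bivalve sinking speeds 0.6(3) mm/s with 1-SD clipping: all in [0.3, 0.9]
  x <- sampleClippedNormal(0.6e-3, 0.3e-3, 1, 1e5)
  expect_true(all(x >= 0.3e-3 & x <= 0.9e-3))
  ## symmetric redistribution preserves the mean (Monte-Carlo, 3 SE)
  y <- sampleClippedNormal(2.4, 2.0, 1, 1e5)
  expect_true(all(y >= 0.4 & y <= 4.4))
  se <- sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - 2.4), 3 * se)

  expect_error(sampleClippedNormal(1, -0.1, 1, 10), "sd")
})

test_that("RK4 advection reproduces uniform transport and is 4th order", {
  ## uniform 0.1 m/s eastward, dt = 1800 s -> 180 m east at the local latitude
  f <- analyticFields(uFun = function(lon, lat, z, t) rep(0.1, length(lon)),
                      vFun = function(lon, lat, z, t) rep(0, length(lon)))
  p0 <- list(lon = -63, lat = 45)
  p1 <- rk4Advect(p0$lon, p0$lat, 1, f, 258, 1800)
  mPerDeg <- 111320 * cos(45 * pi / 180)
  expect_equal((p1$lon - p0$lon) * mPerDeg, 180, tolerance = 1e-9)
  expect_equal(p1$lat, p0$lat)

  ## zero velocity -> no motion
  f0 <- analyticFields()
  p2 <- rk4Advect(-63, 45, 1, f0, 258, 1800)
  expect_identical(c(p2$lon, p2$lat), c(-63, 45))

  ## solid-body rotation: the field is built so the kernel integrates
  ## dlon/dt = -omega lat, dlat/dt = omega lon (a closed circular orbit)
  omega <- 2 * pi / (10 * 86400)          # 10-day revolution
  lat0 <- 45
  frot <- analyticFields(
    uFun = function(lon, lat, z, t) {
      -omega * (lat - lat0) * (111320 * cos(lat * pi / 180))
    },
    vFun = function(lon, lat, z, t) {
      omega * (lon + 63) * 110574
    },
    lonRange = c(-64, -62), latRange = c(44, 46))
  orbit <- function(nSteps) {
    dt <- 10 * 86400 / nSteps
    lon <- -63 + 0.5; lat <- lat0
    t <- 0
    for (s in seq_len(nSteps)) {
      p <- rk4Advect(lon, lat, 1, frot, t, dt)
      lon <- p$lon; lat <- p$lat
      t <- t + dt / 86400
    }
    sqrt((lon - (-63 + 0.5))^2 + (lat - lat0)^2)
  }
  expect_lt(orbit(1000L), 1e-6 * 0.5)
  ## halving dt shrinks the error ~16x (4th order); compare at coarser
  ## steps where truncation dominates round-off
  expect_lt(orbit(200L), orbit(100L) / 10)

  expect_error(rk4Advect(-80, 45, 1, f0, 258, 1800), "extent")
})

test_that("Milstein diffusion matches its exact moments", {
  ## K = 0: no displacement
  f0 <- analyticFields(kFun = function(lon, lat, z, t) rep(0, length(lon)),
                       dKdxFun = function(lon, lat, z, t) rep(0, length(lon)),
                       dKdyFun = function(lon, lat, z, t) rep(0, length(lon)))
  set.seed(2)
  p <- milsteinDiffuse(rep(-63, 10), rep(45, 10), rep(1, 10), f0, 258, 1800)
  expect_identical(p$lon, rep(-63, 10))

  ## constant K = 10: single-step variance = 2 K dt per axis (3 SE)
  fK <- analyticFields(kFun = function(lon, lat, z, t) rep(10, length(lon)),
                       dKdxFun = function(lon, lat, z, t) rep(0, length(lon)),
                       dKdyFun = function(lon, lat, z, t) rep(0, length(lon)))
  n <- 1e5
  set.seed(3)
  p <- milsteinDiffuse(rep(-63, n), rep(45, n), rep(1, n), fK, 258, 1800)
  dxm <- (p$lon + 63) * 111320 * cos(45 * pi / 180)
  dym <- (p$lat - 45) * 110574
  target <- 2 * 10 * 1800
  seVar <- target * sqrt(2 / (n - 1))
  expect_lt(abs(var(dxm) - target), 3 * seVar)
  expect_lt(abs(var(dym) - target), 3 * seVar)

  ## linear K(x): ensemble mean drift = (dK/dx) dt (3 SE)
  gamma <- 1e-3
  mPerDeg <- 111320 * cos(45 * pi / 180)
  fL <- analyticFields(
    kFun = function(lon, lat, z, t) 10 + gamma * (lon + 63) * mPerDeg,
    dKdxFun = function(lon, lat, z, t) rep(gamma, length(lon)),
    dKdyFun = function(lon, lat, z, t) rep(0, length(lon)))
  set.seed(4)
  p <- milsteinDiffuse(rep(-63, n), rep(45, n), rep(1, n), fL, 258, 1800)
  dxm <- (p$lon + 63) * mPerDeg
  se <- sd(dxm) / sqrt(n)
  expect_lt(abs(mean(dxm) - gamma * 1800), 3 * se)

  ## finite-difference K gradient agrees with the analytic one
  fG <- fL
  fG@analytic$dKdx <- NULL; fG@analytic$dKdy <- NULL
  g <- kGradientAt(fG, -63, 45, 1, 258)
  expect_equal(g$dKdx, gamma, tolerance = 1e-6)
})

test_that("vertical behavior sinks, seeks depth, stops swimming, clamps", {
  dt <- 1800
  ## at the preferred depth: swimming stops, sinking continues
  expect_equal(verticalStep(30, 0.6e-3, 2.4e-3, 30, 150, dt),
               30 + 0.6e-3 * dt)
  ## far above the preferred depth: both terms act downward
  expect_equal(verticalStep(10, 0.6e-3, 2.4e-3, 110, 150, dt),
               10 + (0.6e-3 + 2.4e-3) * dt)
  ## swimming covers only the remaining distance when it would overshoot
  expect_equal(verticalStep(30.001, 0.6e-3, 2.4e-3, 30, 150, dt),
               30.001 + 0.6e-3 * dt - 0.001)
  ## clamped just above the bathymetry and below the surface
  expect_equal(verticalStep(149.9, 1, 0, 200, 150, dt), 149.9)
  expect_equal(verticalStep(5, 0, 1, 0.0, 150, dt), 0.1)
})

test_that("seeding is Poisson-uniform over water with bounded traits", {
  fields <- makeMldAndBathy(makeDoubleGyre(extentKm = 300, cellKm = 10))
  waterKm2 <- sum(!fields@landMask) * 100
  sc <- SimConfig(seedDensity = 1000 / waterKm2, gridRes = 5L, rngSeed = 21L)
  bc <- BehaviorConfig(mode = "preferred_depth")
  coh <- seedCohort(fields, sc, bc)
  ## Poisson count: realized total within +-3 sqrt(1000)
  expect_lt(abs(nParticles(coh) - 1000), 3 * sqrt(1000))
  p <- coh@particles
  ## everyone in water, inside extent
  expect_false(any(isLandAt(fields, p$lon0, p$lat0)))
  ## trait bounds hold for 100% of particles
  expect_true(all(p$wSink >= 0.3e-3 & p$wSink <= 0.9e-3))
  expect_true(all(p$wSwim >= 0.4e-3 & p$wSwim <= 4.4e-3))
  mld0 <- mldAt(fields, p$lon0, p$lat0, rep(sc@spawnDay, nrow(p)))
  expect_true(all(abs(p$zPref - mld0) <= 2 * bc@prefDepthSd + 1e-9))

  ## fixed-depth mode: every initial depth is exactly 1 m
  cohF <- seedCohort(fields, sc, BehaviorConfig(mode = "fixed_depth"))
  expect_true(all(cohF@particles$z0 == 1))

  ## determinism: same seed twice gives bit-identical cohorts
  coh2 <- seedCohort(fields, sc, bc)
  expect_identical(coh@particles, coh2@particles)
})

test_that("still water holds particles in place; bookkeeping is exact", {
  n <- 6L
  f <- analyticFields(k0 = 0)
  f@analytic <- list()   # gridded zeros everywhere
  sc <- SimConfig(seedDensity = 1e-3, gridRes = 5L, rngSeed = 3L,
                  pldDays = 5, competencyDays = 2)
  coh <- seedCohort(f, sc, BehaviorConfig(mode = "fixed_depth"))
  sim <- runSimulation(coh, f)
  p <- sim@particles
  expect_true(all(p$status == "active"))
  expect_identical(p$lon, p$lon0)
  expect_identical(p$lat, p$lat0)
  ## one output record per day per surviving particle
  expect_false(any(is.na(sim@history[, , 1])))
  expect_equal(dim(sim@history)[2], 6L)  # day 0 .. 5
  ## zero-flow identity flow map: every particle settles where it spawned
  fm <- buildFlowMap(resolveSettlement(sim, "FD"))
  expect_identical(fm@pairs$spawnCell, fm@pairs$settleCell)
})

test_that("particles advected into land beach and are excluded downstream", {
  run <- .sharedRun()
  p <- run$sim@particles
  expect_gt(sum(p$status == "beached"), 0)
  fm <- buildFlowMap(run$pd)
  beachedIds <- p$id[p$status == "beached"]
  expect_length(intersect(fm@pairs$id, beachedIds), 0L)
  ## status is monotone: beached particles never acquire a settle cell
  pdp <- run$pd@particles
  expect_false(any(pdp$status == "beached" & !is.na(pdp$settleCell)))
})

test_that("settlement honors case semantics and the competency window", {
  run <- .sharedRun()
  pld <- run$simConfig@pldDays

  ## PD: active particles settle in the cell of their day-45 position
  pd <- run$pd@particles
  settled <- pd[pd$status == "settled", ]
  expect_true(all(settled$settleDay == pld))
  expect_identical(settled$settleCell,
                   assignCell(settled$lon, settled$lat, run$simConfig@gridRes))

  ## SH: same simulation, settlement on first suitable day in 39..45
  sh <- resolveSettlement(run$sim, "SH", habitat = run$habitat)
  expect_identical(sh@history, run$pd@history)
  suitable <- unique(unlist(lapply(run$habitat, function(h) h@cells)))
  shp <- sh@particles
  st <- shp[shp$status == "settled", ]
  expect_gt(nrow(st), 0)
  expect_true(all(st$settleDay >= pld - 6 & st$settleDay <= pld))
  expect_true(all(st$spawnCell %in% suitable))
  expect_true(all(st$settleCell %in% suitable))
  ## first-day rule: no earlier competency-window output sits on habitat
  res <- run$simConfig@gridRes
  for (k in head(order(st$settleDay, decreasing = TRUE), 20)) {
    d <- st$settleDay[k]
    if (d > pld - 6) {
      i <- st$id[k]
      earlier <- (pld - 6):(d - 1)
      cells <- assignCell(sh@history[i, earlier + 1, 1],
                          sh@history[i, earlier + 1, 2], res)
      expect_false(any(cells %in% suitable))
    }
  }
  ## never over habitat in the window -> nonviable
  expect_true(all(shp$status %in% c("settled", "nonviable", "beached", "exited")))
  expect_gt(sum(shp$status == "nonviable"), 0)

  expect_error(resolveSettlement(run$sim, "SH"), "habitat")
})
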