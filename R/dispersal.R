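## Lagrangian transport of larval cohorts: fourth-order Runge-Kutta
## horizontal advection, first-order Milstein horizontal diffusion, and
## vertical sinking-plus-depth-seeking behavior.  Vertical advection and
## diffusion are excluded by design: behavior is assumed to dominate them.

.STATUS_LEVELS <- c("active", "beached", "exited", "settled", "nonviable")

## local meters-per-degree conversion
.mPerDegLon <- function(lat) .M_PER_DEG_LON0 * cos(lat * pi / 180)

#' Clipped normal sampling
#'
#' Draws from a normal distribution in which values falling outside
#' `clipNsd` standard deviations from the mean are redistributed
#' uniformly within that band.  The redistribution is symmetric about the
#' mean, so the mean is preserved.  Draws come from the caller's RNG
#' stream.
#'
#' @param mean,sd distribution parameters (`sd >= 0`).
#' @param clipNsd clip half-width in standard deviations (> 0).
#' @param n number of samples.
#' @return numeric vector in `[mean - clipNsd*sd, mean + clipNsd*sd]`.
#' @export
sampleClippedNormal <- function(mean, sd, clipNsd, n) {
  if (sd < 0) stop("sd must be >= 0")
  if (clipNsd <= 0) stop("clipNsd must be > 0")
  if (n < 1) stop("n must be >= 1")
  x <- stats::rnorm(n, mean, sd)
  lo <- mean - clipNsd * sd
  hi <- mean + clipNsd * sd
  out <- x < lo | x > hi
  if (any(out)) x[out] <- stats::runif(sum(out), lo, hi)
  x
}

## degree displacement per second for metric velocities at given latitude
.degStep <- function(u, v, lat) {
  list(dlon = u / .mPerDegLon(lat), dlat = v / .M_PER_DEG_LAT)
}

#' Fourth-order Runge-Kutta advection step
#'
#' Classical four-stage Runge-Kutta displacement over one time step,
#' horizontal only, with velocity interpolated in space and time and
#' converted from m s^-1 to degrees at each stage's latitude.
#'
#' @param lon,lat,z position vectors (degrees, m positive down).
#' @param fields an [EnvironmentFields-class] object.
#' @param t time (day of year; fractional days within a step).
#' @param dt step length, seconds.
#' @return list of updated `lon`, `lat`.
#' @export
rk4Advect <- function(lon, lat, z, fields, t, dt) {
  if (dt <= 0) stop("dt must be positive")
  if (!all(insideExtent(fields, lon, lat))) stop("position outside field extent")
  .rk4Step(lon, lat, z, fields, t, dt)
}

.rk4Step <- function(lon, lat, z, fields, t, dt) {
  dtd <- dt / 86400            # step in days, for the time axis
  vel <- velocityAt(fields, lon, lat, z, t)
  k1 <- .degStep(vel$u, vel$v, lat)
  vel <- velocityAt(fields, lon + 0.5 * dt * k1$dlon, lat + 0.5 * dt * k1$dlat,
                    z, t + 0.5 * dtd)
  k2 <- .degStep(vel$u, vel$v, lat + 0.5 * dt * k1$dlat)
  vel <- velocityAt(fields, lon + 0.5 * dt * k2$dlon, lat + 0.5 * dt * k2$dlat,
                    z, t + 0.5 * dtd)
  k3 <- .degStep(vel$u, vel$v, lat + 0.5 * dt * k2$dlat)
  vel <- velocityAt(fields, lon + dt * k3$dlon, lat + dt * k3$dlat,
                    z, t + dtd)
  k4 <- .degStep(vel$u, vel$v, lat + dt * k3$dlat)
  list(lon = lon + dt / 6 * (k1$dlon + 2 * k2$dlon + 2 * k3$dlon + k4$dlon),
       lat = lat + dt / 6 * (k1$dlat + 2 * k2$dlat + 2 * k3$dlat + k4$dlat))
}

#' First-order Milstein diffusion step
#'
#' Per horizontal axis, with Wiener increment `dW ~ N(0, dt)`:
#' `displacement = sqrt(2 K) dW + 0.5 (dK/daxis) (dW^2 + dt)`.
#' The deterministic part supplies the well-mixed drift correction, so
#' spatially varying diffusivity does not artificially accumulate
#' particles in low-K regions.  The K gradient is evaluated exactly when
#' the fields carry an analytic backend and by centered finite difference
#' on the grid otherwise.  Draws come from the caller's RNG stream.
#'
#' @inheritParams rk4Advect
#' @return list of updated `lon`, `lat`.
#' @export
milsteinDiffuse <- function(lon, lat, z, fields, t, dt) {
  K <- diffusivityAt(fields, lon, lat, z, t)
  if (any(K < 0)) stop("negative diffusivity")
  g <- kGradientAt(fields, lon, lat, z, t)
  n <- length(lon)
  dWx <- stats::rnorm(n, 0, sqrt(dt))
  dWy <- stats::rnorm(n, 0, sqrt(dt))
  dxm <- sqrt(2 * K) * dWx + 0.5 * g$dKdx * (dWx^2 + dt)
  dym <- sqrt(2 * K) * dWy + 0.5 * g$dKdy * (dWy^2 + dt)
  list(lon = lon + dxm / .mPerDegLon(lat), lat = lat + dym / .M_PER_DEG_LAT)
}

#' Vertical behavior step
#'
#' Net vertical displacement over one step for depth-seeking particles:
#' sinking at `wSink` plus swimming toward the preferred depth `zPref`
#' at up to `wSwimMax`; if the swim leg would overshoot `zPref` within
#' the step, swimming covers only the remaining distance (the particle
#' stops swimming at its preferred depth; sinking continues regardless).
#' The result is clamped to just below the surface and just above the
#' local bathymetry.
#'
#' @param z current depth (m, positive down).
#' @param wSink,wSwimMax,zPref per-particle traits (m s^-1, m).
#' @param bathy local bathymetry (m).
#' @param dt step length, seconds.
#' @param surfaceClearance,bottomClearance clamp margins (m, default 0.1).
#' @return updated depth vector.
#' @export
verticalStep <- function(z, wSink, wSwimMax, zPref, bathy, dt,
                         surfaceClearance = 0.1, bottomClearance = 0.1) {
  swim <- sign(zPref - z) * pmin(wSwimMax * dt, abs(zPref - z))
  zn <- z + wSink * dt + swim
  pmin(pmax(zn, surfaceClearance), pmax(bathy - bottomClearance,
                                        surfaceClearance))
}

#' Seed a particle cohort
#'
#' Places particles quasi-uniformly over the water domain: each water
#' grid cell receives a Poisson(`seedDensity` x cell area) number of
#' particles at uniform positions within the cell, so the expected total
#' equals density times water area.  Per-particle traits (sinking speed,
#' maximum swimming speed, preferred depth around the local mixed-layer
#' depth) are drawn from clipped normal distributions and stay constant
#' for the particle's lifetime.  In fixed-depth mode all particles start
#' (and remain) at the fixed depth.  Seeding is uniform over water
#' regardless of habitat: habitat constrains settlement, not spawning,
#' so the preferred-depth and suitable-habitat cases can share one
#' simulation.
#'
#' @param fields an [EnvironmentFields-class] object.
#' @param simConfig a [SimConfig-class] object (density, seed, grid
#'   resolution, spawn day).
#' @param behaviorConfig a [BehaviorConfig-class] object.
#' @return a [ParticleCohort-class] with status `active` everywhere.
#' @export
seedCohort <- function(fields, simConfig = SimConfig(),
                       behaviorConfig = BehaviorConfig()) {
  water <- which(!fields@landMask, arr.ind = TRUE)
  if (!nrow(water)) stop("empty water domain")
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(simConfig@rngSeed)

  dlon <- diff(fields@lonAxis)[1L]
  dlat <- diff(fields@latAxis)[1L]
  latC <- fields@latAxis[water[, 2L]]
  areaKm2 <- (dlon * .mPerDegLon(latC) / 1000) * (dlat * .M_PER_DEG_LAT / 1000)
  counts <- stats::rpois(nrow(water), simConfig@seedDensity * areaKm2)
  n <- sum(counts)
  if (n == 0L) stop("seed density too low: no particles placed")
  ci <- rep(seq_len(nrow(water)), counts)
  lon <- fields@lonAxis[water[ci, 1L]] + (stats::runif(n) - 0.5) * dlon
  lat <- fields@latAxis[water[ci, 2L]] + (stats::runif(n) - 0.5) * dlat

  bc <- behaviorConfig
  wSink <- sampleClippedNormal(bc@sinkMean, bc@sinkSd, bc@traitClipNsd, n)
  wSwim <- sampleClippedNormal(bc@swimMean, bc@swimSd, bc@traitClipNsd, n)
  if (bc@mode == "preferred_depth") {
    mld0 <- mldAt(fields, lon, lat, rep(simConfig@spawnDay, n))
    zPref <- mld0 + sampleClippedNormal(0, bc@prefDepthSd, bc@prefClipNsd, n)
    bat <- bathyAt(fields, lon, lat)
    zPref <- pmin(pmax(zPref, 0.2), pmax(bat - 0.2, 0.2))
    z0 <- zPref
  } else {
    zPref <- rep(bc@fixedDepth, n)
    z0 <- rep(bc@fixedDepth, n)
  }
  spawnCell <- assignCell(lon, lat, simConfig@gridRes)

  particles <- data.frame(
    id = seq_len(n), lon0 = lon, lat0 = lat, z0 = z0,
    wSink = wSink, wSwim = wSwim, zPref = zPref, spawnCell = spawnCell,
    lon = lon, lat = lat, z = z0,
    status = factor(rep("active", n), levels = .STATUS_LEVELS),
    settleCell = NA_character_, settleDay = NA_integer_,
    stringsAsFactors = FALSE)
  history <- array(NA_real_, c(n, simConfig@pldDays + 1L, 3L),
                   dimnames = list(NULL, NULL, c("lon", "lat", "z")))
  history[, 1L, 1L] <- lon
  history[, 1L, 2L] <- lat
  history[, 1L, 3L] <- z0
  new("ParticleCohort", particles = particles, history = history,
      simConfig = simConfig, behaviorConfig = behaviorConfig, case = "")
}

#' Run a dispersal simulation
#'
#' Advances every active particle with, per calculation step: RK4
#' advection, Milstein diffusion, then the vertical behavior step (or a
#' held depth in fixed-depth mode).  A particle whose new position falls
#' in a land cell -- the zero-velocity region -- is beached and takes no
#' further part; one leaving the lateral field extent is marked exited.
#' Positions are recorded at every output interval for `pldDays` days.
#' With zero diffusivity the run is fully deterministic.
#'
#' @param cohort a freshly seeded [ParticleCohort-class].
#' @param fields an [EnvironmentFields-class] object.
#' @return the cohort with final state and daily history filled in.
#' @export
runSimulation <- function(cohort, fields) {
  sc <- cohort@simConfig
  bc <- cohort@behaviorConfig
  pd <- bc@mode == "preferred_depth"
  stepsPerOut <- as.integer(sc@outputInterval / sc@dt)
  nOut <- as.integer(sc@pldDays * 86400 / sc@outputInterval)
  dtd <- sc@dt / 86400

  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(sc@rngSeed + 1000003L)

  p <- cohort@particles
  lon <- p$lon0; lat <- p$lat0; z <- p$z0
  status <- rep(0L, nrow(p))   # 0 active, 1 beached, 2 exited
  t <- sc@spawnDay
  hist <- cohort@history

  for (out in seq_len(nOut)) {
    for (s in seq_len(stepsPerOut)) {
      act <- which(status == 0L)
      if (!length(act)) break
      la <- lon[act]; pa <- lat[act]; za <- z[act]
      adv <- .rk4Step(la, pa, za, fields, t, sc@dt)
      dif <- milsteinDiffuse(adv$lon, adv$lat, za, fields, t, sc@dt)
      nlon <- dif$lon; nlat <- dif$lat
      if (pd) {
        bat <- bathyAt(fields, nlon, nlat)
        za <- verticalStep(za, p$wSink[act], p$wSwim[act], p$zPref[act],
                           bat, sc@dt)
      }
      inside <- insideExtent(fields, nlon, nlat)
      land <- isLandAt(fields, nlon, nlat)
      beach <- inside & !is.na(land) & land
      status[act[!inside]] <- 2L
      status[act[beach]] <- 1L
      keep <- inside & !beach
      lon[act[keep]] <- nlon[keep]
      lat[act[keep]] <- nlat[keep]
      z[act[keep]] <- za[keep]
      ## beached/exited particles keep their last in-water position
      t <- t + dtd
    }
    day <- out * sc@outputInterval / 86400
    if (day == floor(day)) {
      act <- status == 0L
      hist[act, day + 1L, 1L] <- lon[act]
      hist[act, day + 1L, 2L] <- lat[act]
      hist[act, day + 1L, 3L] <- z[act]
    }
  }

  p$lon <- lon; p$lat <- lat; p$z <- z
  p$status <- factor(ifelse(status == 0L, "active",
                            ifelse(status == 1L, "beached", "exited")),
                     levels = .STATUS_LEVELS)
  cohort@particles <- p
  cohort@history <- hist
  cohort
}

#' Resolve settlement for a simulated cohort
#'
#' Turns trajectories into settlement records under one of the three
#' cases.  `FD` and `PD`: every particle still active at the end of the
#' PLD settles in the cell of its final position.  `SH`: only particles
#' that spawned over suitable habitat are candidates; each settles at its
#' first daily output within the competency window (the final
#' `competencyDays` days of the PLD, i.e. daily checks at days
#' `pld - competency + 1 .. pld`) at which it sits over a suitable cell,
#' and is `nonviable` if that never happens.  Particles that beached or
#' exited retain that status and are excluded from all flow maps.
#'
#' @param cohort a simulated [ParticleCohort-class].
#' @param case `"FD"`, `"PD"` or `"SH"`.
#' @param habitat for `SH`: a [HabitatMap-class] or list of them
#'   (suitability is their union).
#' @return the cohort with `settleCell`, `settleDay`, `status` and `case`
#'   filled in.
#' @export
resolveSettlement <- function(cohort, case = c("FD", "PD", "SH"),
                              habitat = NULL) {
  case <- match.arg(case)
  sc <- cohort@simConfig
  p <- cohort@particles
  res <- sc@gridRes
  pld <- as.integer(sc@pldDays)
  active <- p$status == "active"

  if (case %in% c("FD", "PD")) {
    idx <- which(active)
    if (length(idx)) {
      p$settleCell[idx] <- assignCell(p$lon[idx], p$lat[idx], res)
      p$settleDay[idx] <- pld
      p$status[idx] <- "settled"
    }
  } else {
    if (is.null(habitat)) stop("SH case requires a habitat map")
    if (methods::is(habitat, "HabitatMap")) habitat <- list(habitat)
    suitable <- unique(unlist(lapply(habitat, function(h) h@cells)))
    days <- seq.int(pld - as.integer(sc@competencyDays) + 1L, pld)
    cand <- which(active & p$spawnCell %in% suitable)
    settled <- rep(FALSE, length(cand))
    for (d in days) {
      open <- which(!settled)
      if (!length(open)) break
      i <- cand[open]
      cellD <- assignCell(cohort@history[i, d + 1L, 1L],
                          cohort@history[i, d + 1L, 2L], res)
      hit <- cellD %in% suitable
      if (any(hit)) {
        j <- i[hit]
        p$settleCell[j] <- cellD[hit]
        p$settleDay[j] <- d
        p$status[j] <- "settled"
        settled[open[hit]] <- TRUE
      }
    }
    p$status[active & p$status != "settled"] <- "nonviable"
  }
  cohort@particles <- p
  cohort@case <- case
  cohort
}

#' Write trajectory and settlement tables
#'
#' Trajectories as long-format CSV (`id`, `day`, `lon`, `lat`, `z`) and
#' the settlement table as CSV (`id`, `spawnCell`, `settleCell`,
#' `settleDay`, `status`).
#'
#' @param cohort a [ParticleCohort-class].
#' @param file output path.
#' @export
writeTrajectories <- function(cohort, file) {
  h <- cohort@history
  n <- dim(h)[1L]; nd <- dim(h)[2L]
  df <- data.frame(id = rep(seq_len(n), nd),
                   day = rep(seq_len(nd) - 1L, each = n),
                   lon = as.vector(h[, , 1L]),
                   lat = as.vector(h[, , 2L]),
                   z = as.vector(h[, , 3L]))
  df <- df[!is.na(df$lon), ]
  df <- df[order(df$id, df$day), ]
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeTrajectories
#' @export
writeSettlement <- function(cohort, file) {
  p <- cohort@particles
  utils::write.csv(
    data.frame(id = p$id, spawnCell = p$spawnCell,
               settleCell = p$settleCell, settleDay = p$settleDay,
               status = as.character(p$status)),
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
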