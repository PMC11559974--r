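## Synthetic environmental fixtures: a sheared, seasonally modulated
## double-gyre basin with a land border, plus patchy multi-lineage
## habitat.  The fixture has the statistical/physical structure the
## pipeline assumes -- horizontally sheared flow so fixed-depth and
## preferred-depth transport differ, mid-month-anchored monthly
## variation, zero-velocity land -- without solving any ocean dynamics.

#' Synthetic double-gyre velocity fields
#'
#' Builds an [EnvironmentFields-class] object holding two counter-rotating
#' gyres in a square basin ringed by land.  Velocities derive from the
#' streamfunction `psi = -(U L / pi) sin(pi x/L) sin(2 pi y/L)` (so the
#' flow is non-divergent), scaled with depth by `shearProfile(z)` and in
#' time by a seasonal factor anchored at mid-months.  Gyre centers are
#' stagnation points.  Both an analytic backend (exact evaluation at
#' particle positions) and gridded arrays (bilinear/linear interpolation)
#' are populated; they share one interpolation contract, including the
#' piecewise-linear cyclic time axis.
#'
#' @param extentKm basin edge length including the land ring (default
#'   600 km, giving a cohort run that finishes in minutes at the default
#'   grid spacing).
#' @param cellKm grid spacing (default 10 km).
#' @param lon0,lat0 southwest corner (degrees; default -63, 42, a
#'   northwest-Atlantic-like latitude band).
#' @param gyreStrength peak surface speed scale U (m s^-1, default 0.15).
#' @param shearProfile function depth (m) -> velocity scale factor
#'   (default `exp(-z / 50)`: surface-intensified flow so near-surface and
#'   mixed-layer transport differ appreciably).
#' @param seasonalAmp relative amplitude of the monthly modulation
#'   (default 0.25).
#' @param peakDay day of year of peak flow (default 258, mid-September).
#' @param kHoriz horizontal diffusivity (m^2 s^-1, default 20; constant).
#' @param depthAxis depth levels (m).
#' @param landRingCells width of the land border in grid cells (default 2,
#'   so interpolated velocity is identically zero strictly inside the
#'   outer ring).
#' @param steady if TRUE, drop the time axis (fields frozen at `peakDay`).
#' @return an [EnvironmentFields-class] object; basin geometry and gyre
#'   centers are stored in `@analytic$meta`.
#' @export
makeDoubleGyre <- function(extentKm = 600, cellKm = 10, lon0 = -63, lat0 = 42,
                           gyreStrength = 0.15,
                           shearProfile = function(z) exp(-z / 50),
                           seasonalAmp = 0.25, peakDay = 258, kHoriz = 20,
                           depthAxis = c(1, 5, 10, 20, 30, 40, 50, 60, 80,
                                         100, 125, 150, 200, 300),
                           landRingCells = 2L, steady = FALSE) {
  if (extentKm <= 0 || cellKm <= 0) stop("extent and cell size must be positive")
  n <- round(extentKm / cellKm)
  if (abs(n * cellKm - extentKm) > 1e-9) stop("cellKm must divide extentKm")

  latCenter <- lat0 + (extentKm / 2) / (.M_PER_DEG_LAT / 1000)
  mPerDegLon <- .M_PER_DEG_LON0 * cos(latCenter * pi / 180)
  lonAxis <- lon0 + (seq_len(n) - 0.5) * cellKm * 1000 / mPerDegLon
  latAxis <- lat0 + (seq_len(n) - 0.5) * cellKm * 1000 / .M_PER_DEG_LAT

  landMask <- matrix(FALSE, n, n)
  ring <- as.integer(landRingCells)
  if (ring > 0L) {
    landMask[c(seq_len(ring), n - seq_len(ring) + 1L), ] <- TRUE
    landMask[, c(seq_len(ring), n - seq_len(ring) + 1L)] <- TRUE
  }

  ## water box in km from the basin's southwest corner
  w0 <- ring * cellKm
  L <- extentKm - 2 * w0
  xKm <- function(lon) (lon - lon0) * mPerDegLon / 1000
  yKm <- function(lat) (lat - lat0) * .M_PER_DEG_LAT / 1000

  timeDays <- if (steady) numeric(0) else midMonthDays()
  seasonAnchors <- 1 + seasonalAmp * cos(2 * pi * (midMonthDays() - peakDay) /
                                           .DAYS_PER_YEAR)
  season <- function(t) {
    if (steady) return(rep(1 + seasonalAmp, length(t)))
    ## piecewise-linear between mid-month anchors (cyclic), matching the
    ## gridded time interpolation exactly
    wt <- .timeWeights(midMonthDays(), t)
    (1 - wt$w) * seasonAnchors[wt$i0] + wt$w * seasonAnchors[wt$i1]
  }

  U <- gyreStrength
  uFun <- function(lon, lat, z, t) {
    xt <- (xKm(lon) - w0) / L
    yt <- (yKm(lat) - w0) / L
    inw <- xt >= 0 & xt <= 1 & yt >= 0 & yt <= 1
    out <- -U * sin(pi * xt) * cos(2 * pi * yt) * shearProfile(z) * season(t)
    out[!inw] <- 0
    out
  }
  vFun <- function(lon, lat, z, t) {
    xt <- (xKm(lon) - w0) / L
    yt <- (yKm(lat) - w0) / L
    inw <- xt >= 0 & xt <= 1 & yt >= 0 & yt <= 1
    out <- (U / 2) * cos(pi * xt) * sin(2 * pi * yt) * shearProfile(z) * season(t)
    out[!inw] <- 0
    out
  }
  kFun <- function(lon, lat, z, t) rep(kHoriz, length(lon))

  nt <- max(1L, length(timeDays))
  nz <- length(depthAxis)
  tEval <- if (steady) peakDay else timeDays
  u <- array(0, c(n, n, nz, nt)); v <- array(0, c(n, n, nz, nt))
  K <- array(kHoriz, c(n, n, nz, nt))
  lonG <- rep(lonAxis, times = n)
  latG <- rep(latAxis, each = n)
  for (iz in seq_len(nz)) {
    for (it in seq_len(nt)) {
      uu <- uFun(lonG, latG, rep(depthAxis[iz], n * n), rep(tEval[it], n * n))
      vv <- vFun(lonG, latG, rep(depthAxis[iz], n * n), rep(tEval[it], n * n))
      uu[as.vector(landMask)] <- 0
      vv[as.vector(landMask)] <- 0
      u[, , iz, it] <- uu
      v[, , iz, it] <- vv
    }
  }

  bathy <- matrix(300, n, n); bathy[landMask] <- 0
  mld <- array(40, c(n, n, nt))
  mld[] <- pmin(rep(40, n * n * nt), rep(as.vector(bathy), nt))

  gyreCenters <- data.frame(
    lon = lon0 + (w0 + L / 2) * 1000 / mPerDegLon,
    lat = lat0 + (w0 + L * c(0.25, 0.75)) * 1000 / .M_PER_DEG_LAT)

  analytic <- list(u = uFun, v = vFun, K = kFun,
                   dKdx = function(lon, lat, z, t) rep(0, length(lon)),
                   dKdy = function(lon, lat, z, t) rep(0, length(lon)),
                   meta = list(lon0 = lon0, lat0 = lat0, extentKm = extentKm,
                               cellKm = cellKm, waterOffsetKm = w0,
                               waterSpanKm = L, mPerDegLon = mPerDegLon,
                               gyreStrength = U, peakDay = peakDay,
                               seasonalAmp = seasonalAmp,
                               gyreCenters = gyreCenters,
                               shearProfile = shearProfile, season = season))
  EnvironmentFields(lonAxis = lonAxis, latAxis = latAxis,
                    depthAxis = depthAxis, timeDays = timeDays,
                    u = u, v = v, K = K, mld = mld, bathy = bathy,
                    landMask = landMask, analytic = analytic)
}

#' Grid velocities from a streamfunction
#'
#' Centered-difference curl of a streamfunction sampled on a uniform
#' grid: `u = -dpsi/dy`, `v = dpsi/dx`.  The matching centered-difference
#' divergence of the result vanishes identically (to round-off), which is
#' the discrete counterpart of incompressibility.
#'
#' @param psi matrix of streamfunction values (m^2 s^-1), `[x, y]`.
#' @param dxMeters grid spacing in meters.
#' @return list of matrices `u`, `v` (NA on the one-cell frame where the
#'   centered difference is undefined).
#' @export
gridVelocityFromStream <- function(psi, dxMeters) {
  n <- nrow(psi); m <- ncol(psi)
  u <- matrix(NA_real_, n, m); v <- matrix(NA_real_, n, m)
  u[, 2:(m - 1)] <- -(psi[, 3:m] - psi[, 1:(m - 2)]) / (2 * dxMeters)
  v[2:(n - 1), ] <- (psi[3:n, ] - psi[1:(n - 2), ]) / (2 * dxMeters)
  list(u = u, v = v)
}

#' Add mixed-layer depth and bathymetry to synthetic fields
#'
#' Replaces the placeholder MLD and bathymetry of [makeDoubleGyre()] with
#' a smooth bathymetric bowl (`bathyCoast` at the water edge deepening to
#' `bathyMax` mid-basin) and an MLD field with a gentle west-east spatial
#' gradient and a sinusoidal seasonal cycle sampled at mid-month anchors
#' (deepest at `mldPeakDay`, default mid-February).  Errors if the
#' requested MLD would exceed the bathymetry anywhere over water.
#'
#' @param fields an [EnvironmentFields-class] object from [makeDoubleGyre()].
#' @param mldMean mean mixed-layer depth (m, default 40).
#' @param mldAmplitude seasonal MLD amplitude (m, default 15; 0 gives an
#'   MLD constant in time).
#' @param mldPeakDay day of year of deepest mixed layer (default 46).
#' @param bathyCoast,bathyMax bathymetry at the water edge / basin center
#'   (m, defaults 80 and 300).
#' @return the fields object with `mld` and `bathy` replaced.
#' @export
makeMldAndBathy <- function(fields, mldMean = 40, mldAmplitude = 15,
                            mldPeakDay = 46, bathyCoast = 80, bathyMax = 300) {
  if (mldMean <= 0) stop("mldMean must be positive")
  meta <- fields@analytic$meta
  if (is.null(meta)) stop("fields must come from makeDoubleGyre")
  n <- length(fields@lonAxis)
  nt <- max(1L, length(fields@timeDays))
  xt <- ((fields@lonAxis - meta$lon0) * meta$mPerDegLon / 1000 -
           meta$waterOffsetKm) / meta$waterSpanKm
  yt <- ((fields@latAxis - meta$lat0) * (.M_PER_DEG_LAT / 1000) -
           meta$waterOffsetKm) / meta$waterSpanKm
  xg <- matrix(rep(pmin(pmax(xt, 0), 1), n), n)
  yg <- matrix(rep(pmin(pmax(yt, 0), 1), each = n), n)
  bathy <- bathyCoast + (bathyMax - bathyCoast) * sin(pi * xg) * sin(pi * yg)
  bathy[fields@landMask] <- 0

  tEval <- if (nt == 1L) meta$peakDay else fields@timeDays
  spatial <- mldMean * (0.8 + 0.4 * xg)
  mld <- array(0, c(n, n, nt))
  for (it in seq_len(nt)) {
    mld[, , it] <- spatial + mldAmplitude *
      cos(2 * pi * (tEval[it] - mldPeakDay) / .DAYS_PER_YEAR)
  }
  water <- !fields@landMask
  for (it in seq_len(nt)) {
    if (any(mld[, , it][water] > bathy[water])) {
      stop("mixed-layer depth exceeds bathymetry over water")
    }
  }
  mld[mld < 1] <- 1
  fields@bathy <- bathy
  fields@mld <- mld
  methods::validObject(fields)
  fields
}

#' Water cells of a fields domain at a grid resolution
#'
#' Hexagonal cells containing at least one water grid-cell center.
#'
#' @param fields an [EnvironmentFields-class] object.
#' @param resolution hexagonal grid resolution.
#' @return sorted character vector of cell ids.
#' @export
waterCells <- function(fields, resolution = 5L) {
  w <- which(!fields@landMask, arr.ind = TRUE)
  sort(unique(assignCell(fields@lonAxis[w[, 1L]], fields@latAxis[w[, 2L]],
                         resolution)))
}

#' Synthetic patchy habitat for multiple lineages
#'
#' Grows pairwise-disjoint contiguous habitat patches on the hexagonal
#' grid, one per lineage, emulating a heterogeneous multi-lineage
#' distribution of suitable habitat.  Patch seeds are spread by
#' farthest-point sampling over the water cells and patches grow by
#' seeded random breadth-first accretion, so the result is reproducible
#' for a fixed `rngSeed`.
#'
#' @param fields an [EnvironmentFields-class] object (defines the water
#'   domain).
#' @param resolution hexagonal grid resolution.
#' @param nLineages number of lineages (>= 1, default 3).
#' @param patchCells target patch size in cells (default 40; 1 gives a
#'   single-cell patch).
#' @param rngSeed integer seed.
#' @return list of [HabitatMap-class], one per lineage, pairwise disjoint.
#' @export
makeHabitatPatches <- function(fields, resolution = 5L, nLineages = 3L,
                               patchCells = 40L, rngSeed = 1L) {
  if (nLineages < 1L) stop("nLineages must be >= 1")
  cells <- waterCells(fields, resolution)
  if (!length(cells)) stop("no water cells in domain")
  adj <- lapply(cells, function(cc) intersect(cellNeighbors(cc), cells))
  names(adj) <- cells
  ctr <- cellCenter(cells)

  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(as.integer(rngSeed))

  ## farthest-point seeds over cell centers
  seeds <- integer(nLineages)
  seeds[1L] <- sample.int(length(cells), 1L)
  if (nLineages > 1L) {
    d2min <- (ctr[, 1L] - ctr[seeds[1L], 1L])^2 + (ctr[, 2L] - ctr[seeds[1L], 2L])^2
    for (k in 2:nLineages) {
      seeds[k] <- which.max(d2min)
      d2 <- (ctr[, 1L] - ctr[seeds[k], 1L])^2 + (ctr[, 2L] - ctr[seeds[k], 2L])^2
      d2min <- pmin(d2min, d2)
    }
  }

  owner <- setNames(rep(NA_integer_, length(cells)), cells)
  patches <- lapply(seq_len(nLineages), function(k) cells[seeds[k]])
  owner[cells[seeds]] <- seq_len(nLineages)
  frontier <- lapply(seq_len(nLineages), function(k) cells[seeds[k]])
  sizes <- rep(1L, nLineages)
  repeat {
    grew <- FALSE
    for (k in seq_len(nLineages)) {
      if (sizes[k] >= patchCells || !length(frontier[[k]])) next
      cand <- unique(unlist(adj[frontier[[k]]], use.names = FALSE))
      cand <- cand[is.na(owner[cand])]
      if (!length(cand)) { frontier[[k]] <- character(0); next }
      take <- cand[sample.int(length(cand),
                              min(length(cand), patchCells - sizes[k]))]
      owner[take] <- k
      patches[[k]] <- c(patches[[k]], take)
      frontier[[k]] <- take
      sizes[k] <- sizes[k] + length(take)
      grew <- TRUE
    }
    if (!grew || all(sizes >= patchCells)) break
  }
  out <- lapply(seq_len(nLineages), function(k) {
    HabitatMap(lineage = sprintf("lineage%d", k), cells = sort(patches[[k]]))
  })
  ## lineages must be pairwise disjoint
  all_cells <- unlist(lapply(out, function(h) h@cells))
  if (anyDuplicated(all_cells)) stop("habitat patches overlap")
  out
}

## RNG state bracketing so seeded helpers do not clobber the caller's stream
.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRNG <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
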