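## Field evaluation: one interpolation contract shared by the gridded and
## analytic backends.  Horizontal: bilinear between cell centers, clamped
## at the domain edge.  Vertical: linear between depth levels, clamped.
## Time: piecewise-linear between mid-month anchors, cyclic across the
## December -> January boundary (climatological year of 365 days).

.M_PER_DEG_LAT <- 110574
.M_PER_DEG_LON0 <- 111320
.DAYS_PER_YEAR <- 365

#' Mid-month anchor days
#'
#' Day-of-year of the middle of each calendar month in a 365-day
#' climatological year; monthly fields are anchored at these times.
#'
#' @return numeric vector of length 12.
#' @export
midMonthDays <- function() {
  len <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  cumsum(len) - len / 2
}

#' Construct gridded environmental fields
#'
#' @param lonAxis,latAxis cell-center coordinates (degrees).
#' @param depthAxis depth levels (m, positive down).
#' @param timeDays mid-month anchor days (numeric(0) or length 1 for
#'   steady fields).
#' @param u,v,K 4-d arrays `[lon, lat, depth, time]`.
#' @param mld 3-d array `[lon, lat, time]`.
#' @param bathy,landMask matrices `[lon, lat]`.
#' @param analytic optional analytic backend (list of functions).
#' @return an [EnvironmentFields-class] object.
#' @export
EnvironmentFields <- function(lonAxis, latAxis, depthAxis, timeDays,
                              u, v, K, mld, bathy, landMask,
                              analytic = list()) {
  if (length(timeDays) == 0L) timeDays <- numeric(0)
  new("EnvironmentFields", lonAxis = lonAxis, latAxis = latAxis,
      depthAxis = depthAxis, timeDays = timeDays, u = u, v = v, K = K,
      mld = mld, bathy = bathy, landMask = landMask, analytic = analytic)
}

## nearest containing grid cell index (NA outside the extent)
.cellIndex <- function(axis, x) {
  if (length(axis) == 1L) return(ifelse(abs(x - axis) <= Inf, 1L, NA_integer_))
  half <- diff(axis)[1L] / 2
  i <- findInterval(x, c(axis[1L] - half, axis[-length(axis)] + diff(axis) / 2,
                         axis[length(axis)] + half))
  i[i == 0L | i > length(axis)] <- NA_integer_
  i
}

#' Land test at geographic points
#'
#' TRUE where the containing grid cell is land, FALSE over water, NA
#' outside the lateral field extent.
#'
#' @param fields an [EnvironmentFields-class] object.
#' @param lon,lat query positions.
#' @export
isLandAt <- function(fields, lon, lat) {
  i <- .cellIndex(fields@lonAxis, lon)
  j <- .cellIndex(fields@latAxis, lat)
  out <- rep(NA, length(lon))
  ok <- !is.na(i) & !is.na(j)
  out[ok] <- fields@landMask[cbind(i[ok], j[ok])]
  out
}

#' @rdname isLandAt
#' @export
insideExtent <- function(fields, lon, lat) {
  half_lon <- if (length(fields@lonAxis) > 1L) diff(fields@lonAxis)[1L] / 2 else 0
  half_lat <- if (length(fields@latAxis) > 1L) diff(fields@latAxis)[1L] / 2 else 0
  lon >= min(fields@lonAxis) - half_lon & lon <= max(fields@lonAxis) + half_lon &
    lat >= min(fields@latAxis) - half_lat & lat <= max(fields@latAxis) + half_lat
}

## linear interpolation weights along one clamped axis
.axisWeights <- function(axis, x) {
  n <- length(axis)
  if (n == 1L) return(list(i0 = rep(1L, length(x)), i1 = rep(1L, length(x)),
                           w = rep(0, length(x))))
  x <- pmin(pmax(x, axis[1L]), axis[n])
  i0 <- pmin(pmax(findInterval(x, axis), 1L), n - 1L)
  w <- (x - axis[i0]) / (axis[i0 + 1L] - axis[i0])
  list(i0 = i0, i1 = i0 + 1L, w = w)
}

## cyclic time weights between mid-month anchors
.timeWeights <- function(timeDays, t) {
  nt <- length(timeDays)
  if (nt <= 1L) return(list(i0 = rep(1L, length(t)), i1 = rep(1L, length(t)),
                            w = rep(0, length(t))))
  tm <- t %% .DAYS_PER_YEAR
  i0 <- findInterval(tm, timeDays)
  wrap <- i0 == 0L | i0 == nt
  i1 <- i0 + 1L
  w <- numeric(length(t))
  inb <- !wrap
  w[inb] <- (tm[inb] - timeDays[i0[inb]]) / (timeDays[i1[inb]] - timeDays[i0[inb]])
  if (any(wrap)) {
    span <- .DAYS_PER_YEAR - timeDays[nt] + timeDays[1L]
    dtm <- tm[wrap] - timeDays[nt]
    dtm[dtm < 0] <- dtm[dtm < 0] + .DAYS_PER_YEAR
    w[wrap] <- dtm / span
    i0[wrap] <- nt
    i1[wrap] <- 1L
  }
  list(i0 = i0, i1 = i1, w = w)
}

## 4-d (lon, lat, depth, time) interpolation of a gridded array
.interp4 <- function(fields, arr, lon, lat, z, t) {
  wx <- .axisWeights(fields@lonAxis, lon)
  wy <- .axisWeights(fields@latAxis, lat)
  wz <- .axisWeights(fields@depthAxis, z)
  wt <- .timeWeights(fields@timeDays, t)
  acc <- numeric(length(lon))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) for (dt_ in 0:1) {
    wgt <- (if (dx) wx$w else 1 - wx$w) * (if (dy) wy$w else 1 - wy$w) *
      (if (dz) wz$w else 1 - wz$w) * (if (dt_) wt$w else 1 - wt$w)
    nz_idx <- wgt != 0
    if (!any(nz_idx)) next
    idx <- cbind(if (dx) wx$i1 else wx$i0, if (dy) wy$i1 else wy$i0,
                 if (dz) wz$i1 else wz$i0, if (dt_) wt$i1 else wt$i0)
    acc[nz_idx] <- acc[nz_idx] + wgt[nz_idx] * arr[idx[nz_idx, , drop = FALSE]]
  }
  acc
}

## 3-d (lon, lat, time) interpolation
.interp3 <- function(fields, arr, lon, lat, t) {
  wx <- .axisWeights(fields@lonAxis, lon)
  wy <- .axisWeights(fields@latAxis, lat)
  wt <- .timeWeights(fields@timeDays, t)
  acc <- numeric(length(lon))
  for (dx in 0:1) for (dy in 0:1) for (dt_ in 0:1) {
    wgt <- (if (dx) wx$w else 1 - wx$w) * (if (dy) wy$w else 1 - wy$w) *
      (if (dt_) wt$w else 1 - wt$w)
    nz_idx <- wgt != 0
    if (!any(nz_idx)) next
    idx <- cbind(if (dx) wx$i1 else wx$i0, if (dy) wy$i1 else wy$i0,
                 if (dt_) wt$i1 else wt$i0)
    acc[nz_idx] <- acc[nz_idx] + wgt[nz_idx] * arr[idx[nz_idx, , drop = FALSE]]
  }
  acc
}

#' Field evaluation at particle positions
#'
#' Evaluates velocity, diffusivity (and its horizontal gradient),
#' mixed-layer depth and bathymetry at arbitrary positions and times,
#' using the analytic backend when present and grid interpolation
#' otherwise.  Velocity is forced to exactly zero wherever the containing
#' grid cell is land, in both backends, so that the zero-velocity beaching
#' definition is well defined.
#'
#' @param fields an [EnvironmentFields-class] object.
#' @param lon,lat,z,t query position (degrees, m, day of year).
#' @return `velocityAt`: list with `u`, `v` (m s^-1); `diffusivityAt`:
#'   K (m^2 s^-1); `kGradientAt`: list with `dKdx`, `dKdy` (m s^-1 ...
#'   i.e. m^2 s^-1 per m); `mldAt`, `bathyAt`: m positive down.
#' @export
velocityAt <- function(fields, lon, lat, z, t) {
  an <- fields@analytic
  if (!is.null(an$u)) {
    u <- an$u(lon, lat, z, t)
    v <- an$v(lon, lat, z, t)
  } else {
    u <- .interp4(fields, fields@u, lon, lat, z, t)
    v <- .interp4(fields, fields@v, lon, lat, z, t)
  }
  land <- isLandAt(fields, lon, lat)
  kill <- !is.na(land) & land
  u[kill] <- 0
  v[kill] <- 0
  list(u = u, v = v)
}

#' @rdname velocityAt
#' @export
diffusivityAt <- function(fields, lon, lat, z, t) {
  an <- fields@analytic
  if (!is.null(an$K)) an$K(lon, lat, z, t)
  else .interp4(fields, fields@K, lon, lat, z, t)
}

#' @rdname velocityAt
#' @export
kGradientAt <- function(fields, lon, lat, z, t) {
  an <- fields@analytic
  if (!is.null(an$dKdx) && !is.null(an$dKdy)) {
    return(list(dKdx = an$dKdx(lon, lat, z, t), dKdy = an$dKdy(lon, lat, z, t)))
  }
  ## centered finite difference over half a grid cell
  dlon <- if (length(fields@lonAxis) > 1L) diff(fields@lonAxis)[1L] / 2 else 1e-3
  dlat <- if (length(fields@latAxis) > 1L) diff(fields@latAxis)[1L] / 2 else 1e-3
  kxp <- diffusivityAt(fields, lon + dlon, lat, z, t)
  kxm <- diffusivityAt(fields, lon - dlon, lat, z, t)
  kyp <- diffusivityAt(fields, lon, lat + dlat, z, t)
  kym <- diffusivityAt(fields, lon, lat - dlat, z, t)
  mx <- .M_PER_DEG_LON0 * cos(lat * pi / 180)
  list(dKdx = (kxp - kxm) / (2 * dlon * mx),
       dKdy = (kyp - kym) / (2 * dlat * .M_PER_DEG_LAT))
}

#' @rdname velocityAt
#' @export
mldAt <- function(fields, lon, lat, t) {
  an <- fields@analytic
  if (!is.null(an$mld)) an$mld(lon, lat, t)
  else .interp3(fields, fields@mld, lon, lat, t)
}

#' @rdname velocityAt
#' @export
bathyAt <- function(fields, lon, lat) {
  an <- fields@analytic
  if (!is.null(an$bathy)) an$bathy(lon, lat)
  else {
    wx <- .axisWeights(fields@lonAxis, lon)
    wy <- .axisWeights(fields@latAxis, lat)
    (1 - wx$w) * (1 - wy$w) * fields@bathy[cbind(wx$i0, wy$i0)] +
      wx$w * (1 - wy$w) * fields@bathy[cbind(wx$i1, wy$i0)] +
      (1 - wx$w) * wy$w * fields@bathy[cbind(wx$i0, wy$i1)] +
      wx$w * wy$w * fields@bathy[cbind(wx$i1, wy$i1)]
  }
}

## ---- plain-text gridded container ------------------------------------

#' Read and write gridded fields
#'
#' Plain-text container for gridded fields with CF-like coordinate
#' variables: named coordinate lines (`lon`, `lat`, `depth`, `time`)
#' followed by named array blocks in column-major order.  The analytic
#' backend is not serialized; a round-tripped object evaluates through
#' grid interpolation.
#'
#' @param fields an [EnvironmentFields-class] object.
#' @param file path.
#' @return `writeFields` returns the path invisibly; `readFields` an
#'   [EnvironmentFields-class] object.
#' @export
writeFields <- function(fields, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("larvanet-fields 1", con)
  wv <- function(name, x) {
    writeLines(sprintf("coord %s %d", name, length(x)), con)
    writeLines(paste(sprintf("%.17g", x), collapse = " "), con)
  }
  wv("lon", fields@lonAxis); wv("lat", fields@latAxis)
  wv("depth", fields@depthAxis); wv("time", fields@timeDays)
  wa <- function(name, a) {
    d <- dim(a)
    writeLines(sprintf("array %s %s", name, paste(d, collapse = " ")), con)
    writeLines(paste(sprintf("%.17g", as.numeric(a)), collapse = " "), con)
  }
  wa("u", fields@u); wa("v", fields@v); wa("K", fields@K)
  wa("mld", fields@mld); wa("bathy", fields@bathy)
  writeLines(sprintf("array land %s", paste(dim(fields@landMask), collapse = " ")),
             con)
  writeLines(paste(as.integer(fields@landMask), collapse = " "), con)
  invisible(file)
}

#' @rdname writeFields
#' @export
readFields <- function(file) {
  lines <- readLines(file)
  if (!startsWith(lines[1L], "larvanet-fields")) stop("not a fields file")
  coords <- list(); arrays <- list()
  i <- 2L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    vals <- scan(text = lines[i + 1L], quiet = TRUE)
    if (hdr[1L] == "coord") {
      coords[[hdr[2L]]] <- vals
    } else {
      d <- as.integer(hdr[-(1:2)])
      arrays[[hdr[2L]]] <- array(vals, dim = d)
    }
    i <- i + 2L
  }
  EnvironmentFields(lonAxis = coords$lon, latAxis = coords$lat,
                    depthAxis = coords$depth, timeDays = coords$time,
                    u = arrays$u, v = arrays$v, K = arrays$K,
                    mld = arrays$mld,
                    bathy = arrays$bathy,
                    landMask = arrays$land != 0)
}

#' Read and write habitat maps
#'
#' CSV interchange with columns `lineage`, `cell`.
#'
#' @param habitats list of [HabitatMap-class] objects.
#' @param file path.
#' @export
writeHabitat <- function(habitats, file) {
  df <- do.call(rbind, lapply(habitats, function(h) {
    data.frame(lineage = h@lineage, cell = h@cells)
  }))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeHabitat
#' @export
readHabitat <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  unname(lapply(split(df, df$lineage), function(d) {
    HabitatMap(lineage = d$lineage[1L], cells = d$cell)
  }))
}
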