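## Icosahedral-hexagonal geodesic grid.
##
## A Goldberg-style global hexagonal tessellation with the aperture-7
## hierarchy used by hierarchical hexagonal geospatial indexes: resolution
## r carries 2 + 120 * 7^r cells, of which exactly 12 (one per icosahedron
## vertex) are pentagons.  Cells are Voronoi cells of a triangular lattice
## laid over each icosahedron face; the lattice is the Eisenstein-integer
## lattice Z[tau] (tau = exp(i*pi/3)) scaled by
##   c_r = (2 + 2*tau) * (2 + tau)^r,   |c_r|^2 = 12 * 7^r,
## expressed in the face-edge basis, so face corners are always lattice
## points and adjacent faces agree on their shared edge.  Points are
## assigned by gnomonic projection onto the nearest face followed by
## hexagonal lattice rounding; cell centers falling on a foreign face are
## re-indexed in that face's frame so every physical cell has one id.

# mean Earth radius (authalic), km
.EARTH_RADIUS_KM <- 6371.0072
.TAU_C <- complex(real = 0.5, imaginary = sqrt(3) / 2)

.icosa <- local({
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  ## faces: triples of mutually nearest vertices
  d <- as.matrix(dist(v))
  edge <- min(d[d > 1e-9])
  faces <- t(combn(12L, 3L))
  keep <- apply(faces, 1L, function(f) all(d[f, f][upper.tri(diag(3))] < edge * 1.1))
  faces <- faces[keep, , drop = FALSE]
  stopifnot(nrow(faces) == 20L)
  ## orient counterclockwise seen from outside (positive triple product)
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    if (det(v[f, ]) < 0) faces[k, ] <- f[c(1L, 3L, 2L)]
  }
  ## canonical rotation: smallest vertex index first, preserve cyclic order
  for (k in seq_len(nrow(faces))) {
    f <- faces[k, ]
    i <- which.min(f)
    faces[k, ] <- f[((seq.int(i, i + 2L) - 1L) %% 3L) + 1L]
  }
  faces <- faces[order(faces[, 1L], faces[, 2L], faces[, 3L]), , drop = FALSE]
  A <- v[faces[, 1L], , drop = FALSE]
  B <- v[faces[, 2L], , drop = FALSE]
  C <- v[faces[, 3L], , drop = FALSE]
  n <- A + B + C
  n <- n / sqrt(rowSums(n^2))
  h <- rowSums(A * n)
  E1 <- B - A
  E2 <- C - A
  ## Gram inverses for (u, v) recovery on each face plane
  g11 <- rowSums(E1 * E1); g12 <- rowSums(E1 * E2); g22 <- rowSums(E2 * E2)
  det_g <- g11 * g22 - g12 * g12
  list(verts = v, faces = faces, A = A, B = B, C = C, normals = n, h = h,
       E1 = E1, E2 = E2, g11 = g11, g12 = g12, g22 = g22, detg = det_g)
})

.latticeConst <- function(resolution) {
  (2 + 2 * .TAU_C) * (2 + .TAU_C)^resolution
}

.lonlatToXyz <- function(lon, lat) {
  lam <- lon * pi / 180
  phi <- lat * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

.xyzToLonlat <- function(x) {
  lon <- atan2(x[, 2L], x[, 1L]) * 180 / pi
  lat <- asin(pmin(1, pmax(-1, x[, 3L] / sqrt(rowSums(x^2))))) * 180 / pi
  lon[lon >= 180] <- lon[lon >= 180] - 360
  cbind(lon = lon, lat = lat)
}

.faceOf <- function(xyz) {
  max.col(xyz %*% t(.icosa$normals), ties.method = "first")
}

## gnomonic projection of unit vectors onto face f's plane -> affine (u, v)
.faceUV <- function(xyz, f) {
  n <- .icosa$normals[f, , drop = FALSE]
  s <- .icosa$h[f] / rowSums(xyz * n)
  P <- xyz * s
  d <- P - .icosa$A[f, , drop = FALSE]
  b1 <- rowSums(d * .icosa$E1[f, , drop = FALSE])
  b2 <- rowSums(d * .icosa$E2[f, , drop = FALSE])
  u <- (.icosa$g22[f] * b1 - .icosa$g12[f] * b2) / .icosa$detg[f]
  v <- (.icosa$g11[f] * b2 - .icosa$g12[f] * b1) / .icosa$detg[f]
  cbind(u, v)
}

## nearest Eisenstein integer a + b*tau to complex w (hexagonal rounding)
.hexRound <- function(w) {
  b0 <- Im(w) / (sqrt(3) / 2)
  a0 <- Re(w) - b0 / 2
  ra <- round(a0); rb <- round(b0)
  best_a <- ra; best_b <- rb
  best_d <- rep(Inf, length(w))
  for (da in -1:1) {
    for (db in -1:1) {
      a <- ra + da; b <- rb + db
      d <- Mod(w - (a + b * .TAU_C))
      better <- d < best_d - 1e-15
      best_a[better] <- a[better]
      best_b[better] <- b[better]
      best_d[better] <- d[better]
    }
  }
  cbind(a = best_a, b = best_b)
}

## physical unit vector of lattice point (a, b) in face f's frame
.latticeXyz <- function(f, a, b, cr) {
  zc <- (a + b * .TAU_C) / cr
  v <- Im(zc) / (sqrt(3) / 2)
  u <- Re(zc) - v / 2
  P <- .icosa$A[f, , drop = FALSE] +
    u * .icosa$E1[f, , drop = FALSE] + v * .icosa$E2[f, , drop = FALSE]
  P / sqrt(rowSums(P * P))
}

## corner lattice coords must be exact Eisenstein integers
.cornerTable <- function(res) {
  cr <- .latticeConst(res)
  ab_b <- cr                      # corner B has w = cr
  ab_c <- cr * .TAU_C             # corner C has w = cr * tau
  toAB <- function(w) {
    b <- Im(w) / (sqrt(3) / 2)
    a <- Re(w) - b / 2
    c(round(a), round(b))
  }
  rbind(c(0L, 0L), toAB(ab_b), toAB(ab_c))
}

#' Assign geographic points to hexagonal grid cells
#'
#' Maps longitude/latitude coordinates to cell ids of the icosahedral
#' hexagonal geodesic grid at the given resolution.  The grid follows the
#' aperture-7 hierarchy of hierarchical hexagonal indexes: resolution
#' `r` tessellates the globe into `2 + 120 * 7^r` cells, twelve of which
#' are pentagons (at the icosahedron vertices).  At the default resolution
#' 5 the mean cell area is about 253 km^2, so any two points more than
#' ~20 km apart fall in different cells.
#'
#' @param lon,lat numeric vectors, degrees east in `[-180, 180)` and
#'   degrees north.
#' @param resolution non-negative integer grid resolution (default 5).
#' @return character vector of cell ids, one per input point.  Assignment
#'   is deterministic: the same point always yields the same id.
#' @examples
#' assignCell(c(-63, -63.2), c(44.5, 44.5), resolution = 5)
#' @export
assignCell <- function(lon, lat, resolution = 5L) {
  if (length(lon) != length(lat)) stop("lon and lat must have equal length")
  if (any(!is.finite(lon)) || any(!is.finite(lat)) ||
      any(lat < -90) || any(lat > 90)) {
    stop("invalid coordinates")
  }
  res <- as.integer(resolution)
  if (res < 0L) stop("resolution must be >= 0")
  xyz <- .lonlatToXyz(lon, lat)
  .assignXyz(xyz, res)
}

.assignXyz <- function(xyz, res) {
  cr <- .latticeConst(res)
  corners <- .cornerTable(res)
  f <- .faceOf(xyz)
  out <- character(nrow(xyz))
  for (fc in unique(f)) {
    idx <- which(f == fc)
    uv <- .faceUV(xyz[idx, , drop = FALSE], rep(fc, length(idx)))
    w <- (uv[, 1L] + uv[, 2L] * .TAU_C) * cr
    ab <- .hexRound(w)
    out[idx] <- .canonicalId(rep(fc, length(idx)), ab[, 1L], ab[, 2L], res,
                             cr, corners)
  }
  out
}

## canonical id for lattice points: pentagon ids at corners, foreign-face
## centers re-indexed in their own face's frame
.canonicalId <- function(f, a, b, res, cr, corners, depth = 0L) {
  id <- character(length(f))
  ## corner (pentagon) detection: exact integer comparison
  corner_k <- rep(0L, length(f))
  for (k in 1:3) {
    hit <- a == corners[k, 1L] & b == corners[k, 2L]
    corner_k[hit] <- k
  }
  is_pent <- corner_k > 0L
  if (any(is_pent)) {
    vtx <- .icosa$faces[cbind(f[is_pent], corner_k[is_pent])]
    id[is_pent] <- sprintf("r%d:P%02d", res, vtx)
  }
  hx <- which(!is_pent)
  if (length(hx)) {
    ctr <- .latticeXyz(f[hx], a[hx], b[hx], cr)
    g <- .faceOf(ctr)
    same <- g == f[hx]
    id[hx[same]] <- sprintf("r%d:f%02d:%d:%d", res, f[hx[same]],
                            a[hx[same]], b[hx[same]])
    if (any(!same) && depth < 2L) {
      j <- hx[!same]
      uv <- .faceUV(ctr[!same, , drop = FALSE], g[!same])
      w <- (uv[, 1L] + uv[, 2L] * .TAU_C) * cr
      ab <- .hexRound(w)
      id[j] <- .canonicalId(g[!same], ab[, 1L], ab[, 2L], res, cr, corners,
                            depth + 1L)
    } else if (any(!same)) {
      j <- hx[!same]
      id[j] <- sprintf("r%d:f%02d:%d:%d", res, g[!same], a[j], b[j])
    }
  }
  id
}

.parseCell <- function(ids) {
  m <- regmatches(ids, regexec("^r(\\d+):(?:P(\\d+)|f(\\d+):(-?\\d+):(-?\\d+))$",
                               ids))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) stop("malformed cell id: ", ids[bad][1L])
  res <- as.integer(vapply(m, `[`, "", 2L))
  pent <- vapply(m, `[`, "", 3L)
  list(res = res,
       pent = ifelse(pent == "", NA_integer_, suppressWarnings(as.integer(pent))),
       face = suppressWarnings(as.integer(vapply(m, `[`, "", 4L))),
       a = suppressWarnings(as.integer(vapply(m, `[`, "", 5L))),
       b = suppressWarnings(as.integer(vapply(m, `[`, "", 6L))))
}

#' Cell center coordinates
#'
#' @param ids character vector of cell ids from [assignCell()].
#' @return two-column matrix of `lon`, `lat` cell-center coordinates.
#' @export
cellCenter <- function(ids) {
  p <- .parseCell(ids)
  out <- matrix(NA_real_, length(ids), 2L, dimnames = list(NULL, c("lon", "lat")))
  is_pent <- !is.na(p$pent)
  if (any(is_pent)) {
    out[is_pent, ] <- .xyzToLonlat(.icosa$verts[p$pent[is_pent], , drop = FALSE])
  }
  hx <- which(!is_pent)
  for (j in hx) {
    cr <- .latticeConst(p$res[j])
    out[j, ] <- .xyzToLonlat(.latticeXyz(p$face[j], p$a[j], p$b[j], cr))
  }
  out
}

## angular spacing (radians) between adjacent cell centers near a cell
.cellSpacing <- function(id) {
  p <- .parseCell(id)
  cr <- .latticeConst(p$res)
  if (!is.na(p$pent)) {
    ## use the first face meeting this vertex, step off the corner
    fk <- which(apply(.icosa$faces, 1L, function(f) p$pent %in% f))[1L]
    x1 <- .icosa$verts[p$pent, , drop = FALSE]
    x2 <- .latticeXyz(fk, 1L, 0L, cr)
    ## corner may not be (0,0) on that face; fall back to generic estimate
    d <- acos(pmin(1, sum(x1 * x2)))
    if (d < 1e-12 || d > 1) d <- acos(sum(.icosa$A[fk, ] * .icosa$B[fk, ])) / Mod(cr)
    return(d)
  }
  x1 <- .latticeXyz(p$face, p$a, p$b, cr)
  x2 <- .latticeXyz(p$face, p$a + 1L, p$b, cr)
  acos(pmin(1, sum(x1 * x2)))
}

#' Neighboring cells (grid adjacency oracle)
#'
#' Returns the cells sharing an edge with `id`, found by sampling a ring
#' of points one center-spacing away from the cell center.  Hexagons have
#' six neighbors; the twelve pentagon cells have five.
#'
#' @param id a single cell id.
#' @param nProbe number of probe directions (default 36).
#' @return sorted character vector of neighboring cell ids.
#' @export
cellNeighbors <- function(id, nProbe = 36L) {
  stopifnot(length(id) == 1L)
  p <- .parseCell(id)
  ctr_ll <- cellCenter(id)
  ctr <- .lonlatToXyz(ctr_ll[1L], ctr_ll[2L])[1L, ]
  s <- .cellSpacing(id)
  ## local tangent basis
  up <- if (abs(ctr[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * ctr) * ctr
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ctr[2L] * e1[3L] - ctr[3L] * e1[2L],
          ctr[3L] * e1[1L] - ctr[1L] * e1[3L],
          ctr[1L] * e1[2L] - ctr[2L] * e1[1L])
  th <- seq(0, 2 * pi, length.out = nProbe + 1L)[-(nProbe + 1L)]
  P <- outer(cos(th) * sin(s), e1) + outer(sin(th) * sin(s), e2) +
    outer(rep(cos(s), nProbe), ctr)
  P <- P / sqrt(rowSums(P^2))
  ids <- .assignXyz(P, p$res)
  sort(unique(ids[ids != id]))
}

#' Grid cell counts and areas
#'
#' The grid carries `2 + 120 * 7^resolution` cells globally (aperture-7
#' hierarchy over the 20 icosahedron faces), so the mean cell area is the
#' Earth's surface area divided by that count.
#'
#' @param resolution grid resolution.
#' @return `cellCount`: total number of cells on the globe;
#'   `meanCellAreaKm2`: mean cell area in km^2.
#' @export
cellCount <- function(resolution = 5L) {
  cr <- .latticeConst(as.integer(resolution))
  t_r <- round(Mod(cr)^2)
  10 * t_r + 2
}

#' @rdname cellCount
#' @export
meanCellAreaKm2 <- function(resolution = 5L) {
  4 * pi * .EARTH_RADIUS_KM^2 / cellCount(resolution)
}

#' Pentagon cells of the global grid
#'
#' Every resolution hosts exactly one pentagonal cell at each of the 12
#' icosahedron vertices.  This enumerates them by assigning the vertex
#' coordinates themselves.
#'
#' @param resolution grid resolution.
#' @return character vector of pentagon cell ids.
#' @export
pentagonCells <- function(resolution = 5L) {
  ll <- .xyzToLonlat(.icosa$verts)
  unique(assignCell(ll[, 1L], ll[, 2L], resolution))
}

#' Cell polygon geometry
#'
#' Approximate polygon (vertex ring) for a cell, suitable for GeoJSON
#' export.  Vertices are the centroids of the triangles formed by the cell
#' center and pairs of adjacent neighbor centers, which is exact for a
#' planar Voronoi tessellation of a triangular lattice.
#'
#' @param id a single cell id.
#' @return matrix of `lon`, `lat` vertices (closed ring, first == last).
#' @export
cellPolygon <- function(id) {
  nb <- cellNeighbors(id)
  ctr_ll <- cellCenter(id)
  ctr <- .lonlatToXyz(ctr_ll[1L], ctr_ll[2L])[1L, ]
  nb_ll <- cellCenter(nb)
  nbx <- .lonlatToXyz(nb_ll[, 1L], nb_ll[, 2L])
  ## order neighbors by bearing in the tangent plane
  up <- if (abs(ctr[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * ctr) * ctr; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(ctr[2L] * e1[3L] - ctr[3L] * e1[2L],
          ctr[3L] * e1[1L] - ctr[1L] * e1[3L],
          ctr[1L] * e1[2L] - ctr[2L] * e1[1L])
  d <- nbx - matrix(ctr, nrow(nbx), 3L, byrow = TRUE)
  ang <- atan2(d %*% e2, d %*% e1)
  ord <- order(ang)
  nbx <- nbx[ord, , drop = FALSE]
  k <- nrow(nbx)
  vtx <- matrix(NA_real_, k + 1L, 2L, dimnames = list(NULL, c("lon", "lat")))
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    m <- ctr + nbx[i, ] + nbx[j, ]
    m <- m / sqrt(sum(m^2))
    vtx[i, ] <- .xyzToLonlat(matrix(m, 1L))
  }
  vtx[k + 1L, ] <- vtx[1L, ]
  vtx
}

#' Export cell polygons as GeoJSON
#'
#' @param ids cell ids to export.
#' @param file output path.
#' @param properties optional data.frame of per-cell properties (one row
#'   per id), written into each feature.
#' @return the file path, invisibly.
#' @export
exportCellsGeoJSON <- function(ids, file, properties = NULL) {
  feats <- lapply(seq_along(ids), function(i) {
    ring <- cellPolygon(ids[i])
    props <- list(cell = ids[i])
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) unname(ring[r, ])))))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, file, auto_unbox = TRUE, digits = 10)
  invisible(file)
}
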