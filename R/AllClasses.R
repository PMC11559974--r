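#' @import methods
NULL

#' Gridded environmental fields
#'
#' Container for the hydrographic fields driving a dispersal simulation:
#' horizontal velocity (`u`, `v`, m s^-1), horizontal diffusivity (`K`,
#' m^2 s^-1), mixed-layer depth (`mld`, m positive down), bathymetry
#' (`bathy`, m positive down) and a land mask, on a cell-centered
#' lon/lat/depth grid with a mid-month-anchored monthly time axis
#' (`timeDays`, day of a 365-day climatological year; length 1 for steady
#' fields).  Land cells carry zero velocity by construction — the beaching
#' rule depends on it.  An optional `analytic` slot supplies closed-form
#' field functions evaluated exactly at particle positions; grid arrays
#' and analytic functions share one interpolation contract (bilinear
#' horizontal, linear vertical, piecewise-linear cyclic time between
#' mid-month anchors).
#'
#' @slot lonAxis,latAxis cell-center coordinates, degrees.
#' @slot depthAxis depth levels, m positive down.
#' @slot timeDays mid-month anchors, day of year.
#' @slot u,v,K 4-d arrays `[lon, lat, depth, time]`.
#' @slot mld 3-d array `[lon, lat, time]`.
#' @slot bathy,landMask matrices `[lon, lat]`.
#' @slot analytic optional list of functions (`u`, `v`, `K`, `dKdx`,
#'   `dKdy`) plus metadata; empty for purely gridded fields.
#' @export
setClass("EnvironmentFields",
  representation(lonAxis = "numeric", latAxis = "numeric",
                 depthAxis = "numeric", timeDays = "numeric",
                 u = "array", v = "array", K = "array",
                 mld = "array", bathy = "matrix", landMask = "matrix",
                 analytic = "list"),
  validity = function(object) {
    msg <- character()
    nl <- length(object@lonAxis); np <- length(object@latAxis)
    nz <- length(object@depthAxis); nt <- max(1L, length(object@timeDays))
    for (nm in c("u", "v", "K")) {
      if (!identical(dim(slot(object, nm)), c(nl, np, nz, nt)))
        msg <- c(msg, sprintf("%s must be a [lon, lat, depth, time] array", nm))
    }
    if (!identical(dim(object@mld), c(nl, np, nt)))
      msg <- c(msg, "mld must be a [lon, lat, time] array")
    if (!identical(dim(object@bathy), c(nl, np)) ||
        !identical(dim(object@landMask), c(nl, np)))
      msg <- c(msg, "bathy and landMask must be [lon, lat] matrices")
    if (!length(msg)) {
      if (any(object@K < 0)) msg <- c(msg, "K must be non-negative")
      land <- which(object@landMask)
      if (length(land)) {
        uu <- matrix(object@u, nl * np)
        vv <- matrix(object@v, nl * np)
        if (any(uu[land, ] != 0) || any(vv[land, ] != 0))
          msg <- c(msg, "velocity must be zero over land cells")
      }
      water <- !object@landMask
      if (any(water)) {
        for (k in seq_len(nt)) {
          if (any(object@mld[, , k][water] > object@bathy[water] + 1e-9)) {
            msg <- c(msg, "mld must not exceed bathymetry over water")
            break
          }
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Habitat map for one genetic lineage
#'
#' A set of grid cells (at the analysis resolution) in which a lineage can
#' spawn and settle.  Distinct lineages must be pairwise disjoint.
#'
#' @slot lineage lineage label.
#' @slot cells character vector of suitable cell ids.
#' @export
setClass("HabitatMap",
  representation(lineage = "character", cells = "character"),
  validity = function(object) {
    if (length(object@lineage) != 1L) return("lineage must be a single label")
    if (anyDuplicated(object@cells)) return("duplicate cells in habitat map")
    TRUE
  })

#' Vertical behavior configuration
#'
#' Parameters of the two behavioral modes.  In `fixed_depth` mode
#' particles hold `fixedDepth` (default 1 m, buoyant near-surface larvae).
#' In `preferred_depth` mode each particle is assigned a constant sinking
#' speed, a constant maximum swimming speed, and a preferred depth around
#' the local mixed-layer depth, all drawn from clipped normal
#' distributions: draws falling outside `traitClipNsd` standard deviations
#' (`prefClipNsd` for the depth preference) are redistributed uniformly
#' within that band.  Defaults are bivalve-larva estimates: sinking
#' 0.6(3) mm s^-1, swimming 2.4(2.0) mm s^-1.
#'
#' @slot mode `"fixed_depth"` or `"preferred_depth"`.
#' @slot fixedDepth m, depth held in fixed-depth mode.
#' @slot sinkMean,sinkSd m s^-1.
#' @slot swimMean,swimSd m s^-1.
#' @slot traitClipNsd clip half-width for speeds, in SDs.
#' @slot prefDepthSd m, SD of preferred depth around the local MLD.
#' @slot prefClipNsd clip half-width for depth preference, in SDs.
#' @export
setClass("BehaviorConfig",
  representation(mode = "character", fixedDepth = "numeric",
                 sinkMean = "numeric", sinkSd = "numeric",
                 swimMean = "numeric", swimSd = "numeric",
                 traitClipNsd = "numeric", prefDepthSd = "numeric",
                 prefClipNsd = "numeric"),
  prototype(mode = "fixed_depth", fixedDepth = 1,
            sinkMean = 0.6e-3, sinkSd = 0.3e-3,
            swimMean = 2.4e-3, swimSd = 2.0e-3,
            traitClipNsd = 1, prefDepthSd = 5, prefClipNsd = 2),
  validity = function(object) {
    if (!object@mode %in% c("fixed_depth", "preferred_depth"))
      return("mode must be fixed_depth or preferred_depth")
    if (object@sinkSd < 0 || object@swimSd < 0 || object@prefDepthSd < 0)
      return("standard deviations must be >= 0")
    if (object@traitClipNsd <= 0 || object@prefClipNsd <= 0)
      return("clip bounds must be positive")
    ## clipped-normal supports must stay non-negative for speeds
    if (object@sinkMean - object@traitClipNsd * object@sinkSd < 0 ||
        object@swimMean - object@traitClipNsd * object@swimSd < 0)
      return("speed distributions must be non-negative after clipping")
    TRUE
  })

#' Simulation configuration
#'
#' @slot dt calculation time step, s (default 1800 = 30 min).
#' @slot outputInterval trajectory output interval, s (default daily);
#'   must be a multiple of `dt`.
#' @slot pldDays maximum pelagic larval duration, days (default 45).
#' @slot competencyDays length of the settlement-competency window at the
#'   end of the PLD, days (default 7, i.e. settlement checks at daily
#'   outputs 39..45).
#' @slot spawnDay spawn date as day of the climatological year
#'   (default 258 = September 15).
#' @slot seedDensity particles per km^2 of water (default 1.3).
#' @slot gridRes hexagonal grid resolution for spawn/settlement binning.
#' @slot rngSeed integer seed; all randomness in seeding and transport
#'   derives from it.
#' @export
setClass("SimConfig",
  representation(dt = "numeric", outputInterval = "numeric",
                 pldDays = "numeric", competencyDays = "numeric",
                 spawnDay = "numeric", seedDensity = "numeric",
                 gridRes = "integer", rngSeed = "integer"),
  prototype(dt = 1800, outputInterval = 86400, pldDays = 45,
            competencyDays = 7, spawnDay = 258, seedDensity = 1.3,
            gridRes = 5L, rngSeed = 1L),
  validity = function(object) {
    if (object@dt <= 0) return("dt must be positive")
    if (object@outputInterval %% object@dt != 0)
      return("dt must divide outputInterval")
    if (object@competencyDays >= object@pldDays)
      return("competencyDays must be smaller than pldDays")
    if (object@seedDensity <= 0) return("seedDensity must be positive")
    TRUE
  })

#' Particle cohort
#'
#' Per-particle state of a dispersal simulation: spawn position and cell,
#' behavioral traits (constant over each particle's lifetime), current
#' position, fate, settlement record, and the daily position history.
#' Status is monotone: `active` can change once to `beached`, `exited`,
#' `settled` or `nonviable`, never back.
#'
#' @slot particles data.frame with one row per particle: `id`, `lon0`,
#'   `lat0`, `z0`, `wSink`, `wSwim`, `zPref`, `spawnCell`, `lon`, `lat`,
#'   `z`, `status`, `settleCell`, `settleDay`.
#' @slot history array `[particle, day 0..pld, c(lon, lat, z)]` of daily
#'   output positions (NA after a particle's removal).
#' @slot simConfig,behaviorConfig the configurations used.
#' @slot case settlement case label ("", "FD", "PD" or "SH").
#' @export
setClass("ParticleCohort",
  representation(particles = "data.frame", history = "array",
                 simConfig = "SimConfig", behaviorConfig = "BehaviorConfig",
                 case = "character"),
  prototype(case = ""))

#' Flow map
#'
#' The reduction of each surviving particle's trajectory to a single
#' (spawn cell, settlement cell) transition.  Intermediate bins traversed
#' are deliberately not represented.
#'
#' @slot pairs data.frame `id`, `spawnCell`, `settleCell`, one row per
#'   settled particle.
#' @slot case settlement case label.
#' @slot resolution grid resolution of the cell ids.
#' @export
setClass("FlowMap",
  representation(pairs = "data.frame", case = "character",
                 resolution = "integer"),
  validity = function(object) {
    need <- c("id", "spawnCell", "settleCell")
    if (!all(need %in% names(object@pairs)))
      return("pairs must have id, spawnCell, settleCell")
    TRUE
  })

#' Transport network
#'
#' Directed weighted network on grid cells: link weight i -> j is the
#' probability that a particle spawning in i settles in j, so each node's
#' out-weights sum to one (row-stochastic; the network approximates a
#' Markov chain).  Raw transition counts are retained alongside the
#' probabilities; self-loops are permitted.
#'
#' @slot nodes sorted cell ids (every settle cell is also a spawn cell).
#' @slot edges data.frame `from`, `to`, `count`, `prob`.
#' @slot case,resolution provenance of the underlying flow map.
#' @export
setClass("TransportNetwork",
  representation(nodes = "character", edges = "data.frame",
                 case = "character", resolution = "integer"),
  validity = function(object) {
    e <- object@edges
    if (!all(c("from", "to", "count", "prob") %in% names(e)))
      return("edges must have from, to, count, prob")
    if (nrow(e)) {
      if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
        return("edge endpoints must be nodes")
      rs <- tapply(e$prob, factor(e$from, levels = object@nodes), sum)
      rs[is.na(rs)] <- 0
      if (any(abs(rs - 1) > 1e-12))
        return("outgoing probabilities must sum to 1 per node")
    }
    TRUE
  })

#' Node and link flows of a transport network
#'
#' Stationary visit rates of the random walk guiding the map equation:
#' with probability `1 - tau` the walker follows links, with probability
#' `tau` it teleports proportionally to total in-link weight.  Link flows
#' use the teleportation-free step (unrecorded teleportation), so
#' `sum(p) == 1` and `sum(flow) == 1`.
#'
#' @slot nodes node ids.
#' @slot p stationary visit rates.
#' @slot edges data.frame `from`, `to` (integer node indices), `flow`.
#' @slot tau teleportation rate used.
#' @export
setClass("NodeFlow",
  representation(nodes = "character", p = "numeric", edges = "data.frame",
                 tau = "numeric"),
  validity = function(object) {
    if (length(object@p) != length(object@nodes))
      return("p must have one entry per node")
    if (abs(sum(object@p) - 1) > 1e-9) return("node flows must sum to 1")
    if (any(object@p <= 0)) return("node flows must be positive")
    TRUE
  })

#' Map-equation search configuration
#'
#' @slot markovTime Markov time `t > 0` (default 2): inter-community
#'   flows are scaled by `t` inside the codelength, so larger `t` makes
#'   boundaries costlier and communities coarser.
#' @slot tau teleportation rate in `[0, 1)` (default 0.15).
#' @slot nSeeds ensemble size; seeds `0 .. nSeeds-1` (default 100).
#' @slot outerLoops restarts of the greedy search per seed (default 20).
#' @slot tol convergence tolerance (bits) for accepting a move.
#' @export
setClass("MapEqConfig",
  representation(markovTime = "numeric", tau = "numeric", nSeeds = "integer",
                 outerLoops = "integer", tol = "numeric"),
  prototype(markovTime = 2, tau = 0.15, nSeeds = 100L, outerLoops = 20L,
            tol = 1e-12),
  validity = function(object) {
    if (object@markovTime <= 0) return("markovTime must be > 0")
    if (object@tau < 0 || object@tau >= 1) return("tau must be in [0, 1)")
    if (object@nSeeds < 1L || object@outerLoops < 1L)
      return("nSeeds and outerLoops must be >= 1")
    TRUE
  })

#' Two-level network partition
#'
#' @slot membership named integer vector: node id -> community id
#'   (contiguous from 1, every community nonempty).
#' @slot codelength map-equation codelength of the partition, bits.
#' @slot markovTime Markov time the codelength was evaluated at.
#' @slot seed RNG seed that produced the partition (NA for exact or
#'   external partitions).
#' @export
setClass("Partition",
  representation(membership = "integer", codelength = "numeric",
                 markovTime = "numeric", seed = "integer"),
  prototype(codelength = NA_real_, markovTime = 1, seed = NA_integer_),
  validity = function(object) {
    m <- object@membership
    if (is.null(names(m))) return("membership must be named by node id")
    if (length(m)) {
      ids <- sort(unique(m))
      if (!identical(ids, seq_len(max(m))))
        return("community ids must be contiguous from 1")
    }
    TRUE
  })

#' Community classification thresholds
#'
#' @slot delta minimum coherence-fortress difference for a source/sink
#'   call (default 0.05).
#' @slot h high/low cutoff for impermeable/permeable (default 0.95).
#' @export
setClass("ClassifierConfig",
  representation(delta = "numeric", h = "numeric"),
  prototype(delta = 0.05, h = 0.95),
  validity = function(object) {
    if (object@delta <= 0 || object@delta >= 1) return("delta must be in (0, 1)")
    if (object@h <= 0 || object@h >= 1) return("h must be in (0, 1)")
    TRUE
  })

## ---- constructors ----------------------------------------------------

#' @rdname BehaviorConfig-class
#' @param mode,fixedDepth,sinkMean,sinkSd,swimMean,swimSd,traitClipNsd,prefDepthSd,prefClipNsd see slots.
#' @export
BehaviorConfig <- function(mode = c("fixed_depth", "preferred_depth"),
                           fixedDepth = 1,
                           sinkMean = 0.6e-3, sinkSd = 0.3e-3,
                           swimMean = 2.4e-3, swimSd = 2.0e-3,
                           traitClipNsd = 1, prefDepthSd = 5,
                           prefClipNsd = 2) {
  new("BehaviorConfig", mode = match.arg(mode), fixedDepth = fixedDepth,
      sinkMean = sinkMean, sinkSd = sinkSd, swimMean = swimMean,
      swimSd = swimSd, traitClipNsd = traitClipNsd,
      prefDepthSd = prefDepthSd, prefClipNsd = prefClipNsd)
}

#' @rdname SimConfig-class
#' @param dt,outputInterval,pldDays,competencyDays,spawnDay,seedDensity,gridRes,rngSeed see slots.
#' @export
SimConfig <- function(dt = 1800, outputInterval = 86400, pldDays = 45,
                      competencyDays = 7, spawnDay = 258, seedDensity = 1.3,
                      gridRes = 5L, rngSeed = 1L) {
  new("SimConfig", dt = dt, outputInterval = outputInterval,
      pldDays = pldDays, competencyDays = competencyDays,
      spawnDay = spawnDay, seedDensity = seedDensity,
      gridRes = as.integer(gridRes), rngSeed = as.integer(rngSeed))
}

#' @rdname MapEqConfig-class
#' @param markovTime,tau,nSeeds,outerLoops,tol see slots.
#' @export
MapEqConfig <- function(markovTime = 2, tau = 0.15, nSeeds = 100L,
                        outerLoops = 20L, tol = 1e-12) {
  new("MapEqConfig", markovTime = markovTime, tau = tau,
      nSeeds = as.integer(nSeeds), outerLoops = as.integer(outerLoops),
      tol = tol)
}

#' @rdname ClassifierConfig-class
#' @param delta,h see slots.
#' @export
ClassifierConfig <- function(delta = 0.05, h = 0.95) {
  new("ClassifierConfig", delta = delta, h = h)
}

#' @rdname HabitatMap-class
#' @param lineage,cells see slots.
#' @export
HabitatMap <- function(lineage, cells) {
  new("HabitatMap", lineage = lineage, cells = unique(as.character(cells)))
}

## ---- show methods ----------------------------------------------------

setMethod("show", "EnvironmentFields", function(object) {
  cat(sprintf("EnvironmentFields: %d x %d grid, %d depth levels, %s\n",
              length(object@lonAxis), length(object@latAxis),
              length(object@depthAxis),
              if (length(object@timeDays) > 1L)
                sprintf("%d monthly anchors", length(object@timeDays))
              else "steady"))
  cat(sprintf("  lon [%.3f, %.3f], lat [%.3f, %.3f], water cells: %d\n",
              min(object@lonAxis), max(object@lonAxis),
              min(object@latAxis), max(object@latAxis),
              sum(!object@landMask)))
  if (length(object@analytic)) cat("  analytic backend present\n")
})

setMethod("show", "HabitatMap", function(object) {
  cat(sprintf("HabitatMap '%s': %d suitable cells\n",
              object@lineage, length(object@cells)))
})

setMethod("show", "ParticleCohort", function(object) {
  st <- table(object@particles$status)
  cat(sprintf("ParticleCohort: %d particles%s\n", nrow(object@particles),
              if (nzchar(object@case)) paste0(" [case ", object@case, "]") else ""))
  cat("  ", paste(sprintf("%s: %d", names(st), st), collapse = ", "), "\n")
})

setMethod("show", "FlowMap", function(object) {
  cat(sprintf("FlowMap [%s]: %d transitions, %d spawn cells, %d settle cells\n",
              object@case, nrow(object@pairs),
              length(unique(object@pairs$spawnCell)),
              length(unique(object@pairs$settleCell))))
})

setMethod("show", "TransportNetwork", function(object) {
  cat(sprintf("TransportNetwork [%s]: %d nodes, %d links, %d particles\n",
              object@case, length(object@nodes), nrow(object@edges),
              sum(object@edges$count)))
})

setMethod("show", "NodeFlow", function(object) {
  cat(sprintf("NodeFlow: %d nodes, %d link flows, tau = %g\n",
              length(object@nodes), nrow(object@edges), object@tau))
})

setMethod("show", "Partition", function(object) {
  cat(sprintf("Partition: %d nodes in %d communities, codelength %.6f bits (t = %g)\n",
              length(object@membership), nCommunities(object),
              object@codelength, object@markovTime))
})

## ---- accessors -------------------------------------------------------

#' Accessors for larvanet objects
#'
#' Small accessor set: `nParticles()` and `particleStatus()` for cohorts,
#' `flowPairs()` for flow maps, `networkEdges()`/`networkNodes()` for
#' transport networks, `membership()`/`codelength()`/`nCommunities()` for
#' partitions.
#'
#' @param object a larvanet object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nParticles", function(object) standardGeneric("nParticles"))
#' @rdname accessors
#' @export
setMethod("nParticles", "ParticleCohort",
          function(object) nrow(object@particles))

#' @rdname accessors
#' @export
setGeneric("particleStatus", function(object) standardGeneric("particleStatus"))
#' @rdname accessors
#' @export
setMethod("particleStatus", "ParticleCohort",
          function(object) object@particles$status)

#' @rdname accessors
#' @export
setGeneric("flowPairs", function(object) standardGeneric("flowPairs"))
#' @rdname accessors
#' @export
setMethod("flowPairs", "FlowMap", function(object) object@pairs)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "TransportNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setMethod("networkNodes", "TransportNetwork", function(object) object@nodes)

#' @rdname accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))
#' @rdname accessors
#' @export
setMethod("membership", "Partition", function(object) object@membership)

#' @rdname accessors
#' @export
setGeneric("codelength", function(object) standardGeneric("codelength"))
#' @rdname accessors
#' @export
setMethod("codelength", "Partition", function(object) object@codelength)

#' @rdname accessors
#' @export
setGeneric("nCommunities", function(object) standardGeneric("nCommunities"))
#' @rdname accessors
#' @export
setMethod("nCommunities", "Partition", function(object) {
  if (!length(object@membership)) 0L else max(object@membership)
})
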