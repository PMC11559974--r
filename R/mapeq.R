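## Two-level map equation on directed weighted networks.
##
## The codelength of a partition M is
##   L(M) = q H(Q) + sum_m p_m H(P_m)
## where q is the total module-enter flow, Q the normalized enter flows,
## p_m the module codebook rate (member visit rates plus module exit
## flow) and P_m its normalized distribution.  Markov time t scales every
## module-enter and module-exit flow linearly inside the codelength,
## leaving node visit rates and intra-module flows untouched: at t = 1
## this is the standard two-level map equation; larger t makes crossing
## community boundaries costlier, so minimization yields fewer, larger
## communities.  Entropies are in bits with the convention 0 log 0 = 0.

.plogp <- function(x) {
  out <- numeric(length(x))
  nz <- x > 0
  out[nz] <- x[nz] * log2(x[nz])
  out
}

#' Node and link flows of a transport network
#'
#' Computes stationary visit rates of the random walk underlying the map
#' equation: with probability `1 - tau` the walker follows out-links
#' (weights = transition probabilities), with probability `tau` it
#' teleports to nodes proportionally to their total in-link weight
#' ("smart", unrecorded teleportation).  Link flows are the
#' teleportation-free step `f_ij = p_i w_ij`, so teleportation moves are
#' never encoded; they only regularize the stationary distribution on
#' reducible networks.  Solved by power iteration to a 1e-12 tolerance.
#'
#' @param network a [TransportNetwork-class] object (row-stochastic).
#' @param tau teleportation rate in `[0, 1)` (default 0.15).
#' @return a [NodeFlow-class] object.
#' @export
computeNodeFlow <- function(network, tau = 0.15) {
  nodes <- network@nodes
  n <- length(nodes)
  e <- network@edges
  from <- match(e$from, nodes)
  to <- match(e$to, nodes)
  rs <- tapply(e$prob, factor(from, levels = seq_len(n)), sum)
  rs[is.na(rs)] <- 0
  if (any(abs(rs - 1) > 1e-9)) stop("network is not row-stochastic")

  inw <- tapply(e$prob, factor(to, levels = seq_len(n)), sum)
  inw[is.na(inw)] <- 0
  ## vanishing uniform floor: keeps visit rates strictly positive on
  ## nodes without in-links without materially changing the distribution
  tele <- as.numeric(inw) + 1e-12 * max(max(inw), 1)
  tele <- tele / sum(tele)

  p <- rep(1 / n, n)
  for (iter in seq_len(20000L)) {
    contrib <- p[from] * e$prob
    flowalong <- numeric(n)
    tmp <- rowsum(contrib, to)
    flowalong[as.integer(rownames(tmp))] <- tmp
    pn <- (1 - tau) * flowalong + tau * tele
    pn <- pn / sum(pn)
    if (max(abs(pn - p)) < 1e-12) { p <- pn; break }
    p <- pn
  }
  flow <- p[from] * e$prob
  new("NodeFlow", nodes = nodes, p = as.numeric(p),
      edges = data.frame(from = from, to = to, flow = flow), tau = tau)
}

## per-module aggregates used by both the codelength and the optimizer
.moduleStats <- function(p, edges, memb, nMod) {
  sumP <- numeric(nMod)
  tmp <- rowsum(p, memb)
  sumP[as.integer(rownames(tmp))] <- tmp
  mf <- memb[edges$from]
  mt <- memb[edges$to]
  x <- edges$flow
  ext <- mf != mt
  exitF <- enterF <- numeric(nMod)
  if (any(ext)) {
    ex <- rowsum(x[ext], mf[ext], reorder = TRUE)
    exitF[as.integer(rownames(ex))] <- ex
    en <- rowsum(x[ext], mt[ext], reorder = TRUE)
    enterF[as.integer(rownames(en))] <- en
  }
  list(sumP = sumP, exitF = exitF, enterF = enterF)
}

#' Two-level map-equation codelength
#'
#' Codelength in bits of a two-level partition of a flow network, with
#' module-enter and module-exit flows scaled by the Markov time.
#' Self-loops never contribute to exit or enter flow.
#'
#' @param nodeFlow a [NodeFlow-class] object.
#' @param partition a [Partition-class], or a named/plain integer vector
#'   of community ids aligned with `nodeFlow@nodes`.
#' @param markovTime Markov time `t > 0` (default 1).
#' @return codelength in bits.
#' @export
mapEquation <- function(nodeFlow, partition, markovTime = 1) {
  memb <- .membershipVector(nodeFlow, partition)
  nMod <- max(memb)
  st <- .moduleStats(nodeFlow@p, nodeFlow@edges, memb, nMod)
  t <- markovTime
  qm <- t * st$enterF
  q <- sum(qm)
  indexTerm <- .plogp(q) - sum(.plogp(qm))
  exitT <- t * st$exitF
  pmod <- st$sumP + exitT
  moduleTerm <- sum(.plogp(pmod)) - sum(.plogp(exitT)) - sum(.plogp(nodeFlow@p))
  indexTerm + moduleTerm
}

.membershipVector <- function(nodeFlow, partition) {
  m <- if (methods::is(partition, "Partition")) partition@membership
  else partition
  if (!is.null(names(m)) && !is.null(nodeFlow@nodes) &&
      all(nodeFlow@nodes %in% names(m))) {
    m <- m[nodeFlow@nodes]
  }
  if (length(m) != length(nodeFlow@p)) stop("partition does not match flow nodes")
  m <- as.integer(m)
  ## relabel to contiguous ids
  match(m, sort(unique(m)))
}

## ---- greedy two-level search ----------------------------------------

## One greedy level: repeated single-node moves to the neighboring module
## with the best codelength decrease, on a (possibly aggregated) network
## with node weights p and edge flows.  Works with search terms that drop
## the partition-independent sum of node-rate entropies, so deltas equal
## true codelength deltas.
.greedyMoves <- function(p, eFrom, eTo, eFlow, memb, t, tol) {
  n <- length(p)
  ## adjacency lists excluding self-loops
  outAdj <- vector("list", n); inAdj <- vector("list", n)
  sl <- eFrom == eTo
  of <- eFrom[!sl]; ot <- eTo[!sl]; ofl <- eFlow[!sl]
  if (length(of)) {
    os <- split(seq_along(of), of)
    for (k in names(os)) outAdj[[as.integer(k)]] <- os[[k]]
    is_ <- split(seq_along(ot), ot)
    for (k in names(is_)) inAdj[[as.integer(k)]] <- is_[[k]]
  }
  outTot <- numeric(n); inTot <- numeric(n)
  if (length(of)) {
    tmp <- rowsum(ofl, of); outTot[as.integer(rownames(tmp))] <- tmp
    tmp <- rowsum(ofl, ot); inTot[as.integer(rownames(tmp))] <- tmp
  }

  nMod <- max(memb)
  sumP <- numeric(nMod); exitF <- numeric(nMod); enterF <- numeric(nMod)
  tmp <- rowsum(p, memb); sumP[as.integer(rownames(tmp))] <- tmp
  mf <- memb[of]; mt <- memb[ot]; ext <- mf != mt
  if (any(ext)) {
    tmp <- rowsum(ofl[ext], mf[ext]); exitF[as.integer(rownames(tmp))] <- tmp
    tmp <- rowsum(ofl[ext], mt[ext]); enterF[as.integer(rownames(tmp))] <- tmp
  }
  Q <- sum(enterF)
  sumPlogpEnter <- sum(.plogp(t * enterF))

  modTerm <- function(sp, ex) .plogp(sp + t * ex) - .plogp(t * ex)

  improved_any <- FALSE
  repeat {
    improved <- FALSE
    order_ <- sample.int(n)
    for (i in order_) {
      A <- memb[i]
      ## flows from/to i aggregated by module
      oi <- outAdj[[i]]; ii <- inAdj[[i]]
      outTo <- if (length(oi)) {
        v <- rowsum(ofl[oi], memb[ot[oi]])
        stats::setNames(as.numeric(v), rownames(v))
      } else stats::setNames(numeric(0), character(0))
      inFrom <- if (length(ii)) {
        v <- rowsum(ofl[ii], memb[of[ii]])
        stats::setNames(as.numeric(v), rownames(v))
      } else stats::setNames(numeric(0), character(0))
      cand <- sort(unique(as.integer(c(names(outTo), names(inFrom)))))
      cand <- cand[cand != A]
      if (!length(cand)) next

      gA <- function(M) if (!is.na(idx <- match(as.character(M), names(outTo)))) outTo[[idx]] else 0
      hA <- function(M) if (!is.na(idx <- match(as.character(M), names(inFrom)))) inFrom[[idx]] else 0

      out_iA <- gA(A); in_iA <- hA(A)
      ## stats for A without i
      spA <- sumP[A] - p[i]
      exA <- exitF[A] - (outTot[i] - out_iA) + in_iA
      enA <- enterF[A] - (inTot[i] - in_iA) + out_iA
      baseQ <- Q - enterF[A]
      baseS <- sumPlogpEnter - .plogp(t * enterF[A])
      oldLocal <- modTerm(sumP[A], exitF[A])

      bestDelta <- -tol
      bestB <- NA_integer_
      bestNew <- NULL
      for (B in cand) {
        out_iB <- gA(B); in_iB <- hA(B)
        spB <- sumP[B] + p[i]
        exB <- exitF[B] + (outTot[i] - out_iB) - in_iB
        enB <- enterF[B] + (inTot[i] - in_iB) - out_iB
        newQ <- baseQ - enterF[B] + enA + enB
        newS <- baseS - .plogp(t * enterF[B]) + .plogp(t * enA) + .plogp(t * enB)
        dIndex <- (.plogp(t * newQ) - newS) - (.plogp(t * Q) - sumPlogpEnter)
        dModule <- (modTerm(spA, exA) + modTerm(spB, exB)) -
          (oldLocal + modTerm(sumP[B], exitF[B]))
        delta <- dIndex + dModule
        if (delta < bestDelta) {
          bestDelta <- delta
          bestB <- B
          bestNew <- list(spB = spB, exB = exB, enB = enB,
                          newQ = newQ, newS = newS)
        }
      }
      if (!is.na(bestB)) {
        memb[i] <- bestB
        sumP[A] <- spA; exitF[A] <- exA; enterF[A] <- enA
        sumP[bestB] <- bestNew$spB
        exitF[bestB] <- bestNew$exB
        enterF[bestB] <- bestNew$enB
        Q <- bestNew$newQ
        sumPlogpEnter <- bestNew$newS
        improved <- TRUE
        improved_any <- TRUE
      }
    }
    if (!improved) break
  }
  list(memb = memb, improved = improved_any)
}

## aggregate a network by module membership
.aggregateNet <- function(p, eFrom, eTo, eFlow, memb) {
  nMod <- max(memb)
  sp <- numeric(nMod)
  tmp <- rowsum(p, memb)
  sp[as.integer(rownames(tmp))] <- tmp
  key <- (memb[eFrom] - 1L) * nMod + memb[eTo]
  agg <- rowsum(eFlow, key)
  k <- as.integer(rownames(agg))
  list(p = sp, from = ((k - 1L) %/% nMod) + 1L, to = ((k - 1L) %% nMod) + 1L,
       flow = as.numeric(agg))
}

## full search from singletons: node-level moves, aggregation cycles, and
## node-level fine-tuning, repeated until the codelength stops improving
.greedyRun <- function(p, edges, t, tol) {
  n <- length(p)
  memb <- seq_len(n)
  eF <- edges$from; eT <- edges$to; eW <- edges$flow
  repeat {
    res <- .greedyMoves(p, eF, eT, eW, memb, t, tol)
    memb <- match(res$memb, sort(unique(res$memb)))
    improvedOuter <- res$improved
    ## aggregate modules into super-nodes and move those, recursively
    repeat {
      if (max(memb) <= 1L) break
      agg <- .aggregateNet(p, eF, eT, eW, memb)
      res2 <- .greedyMoves(agg$p, agg$from, agg$to, agg$flow,
                           seq_along(agg$p), t, tol)
      if (!res2$improved) break
      superMemb <- match(res2$memb, sort(unique(res2$memb)))
      memb <- superMemb[memb]
      improvedOuter <- TRUE
    }
    if (!improvedOuter) break
  }
  memb
}

#' Greedy two-level map-equation optimization
#'
#' Stochastic greedy search for the minimum-codelength two-level
#' partition: seeded random node orders, repeated single-node moves to
#' the neighboring module with the best codelength decrease (strict
#' improvement required; candidate modules scanned in ascending id for
#' determinism), aggregation of modules into a super-network and
#' recursion, restarted `outerLoops` times keeping the best partition.
#' Deterministic given (network, config, seed).
#'
#' @param nodeFlow a [NodeFlow-class] object.
#' @param config a [MapEqConfig-class] object.
#' @param seed integer RNG seed for this run.
#' @return a [Partition-class] object.
#' @export
optimizePartition <- function(nodeFlow, config = MapEqConfig(), seed = 0L) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(as.integer(seed))
  t <- config@markovTime
  p <- nodeFlow@p
  edges <- nodeFlow@edges
  best <- NULL
  bestL <- Inf
  for (l in seq_len(config@outerLoops)) {
    memb <- .greedyRun(p, edges, t, config@tol)
    memb <- match(memb, sort(unique(memb)))
    L <- mapEquation(nodeFlow, memb, t)
    if (L < bestL - config@tol) {
      bestL <- L
      best <- memb
    }
  }
  ## never worse than the single-module partition
  oneL <- mapEquation(nodeFlow, rep(1L, length(p)), t)
  if (oneL < bestL) {
    best <- rep(1L, length(p))
    bestL <- oneL
  }
  new("Partition",
      membership = stats::setNames(best, nodeFlow@nodes),
      codelength = bestL, markovTime = t, seed = as.integer(seed))
}

#' Seed-ensemble community detection
#'
#' Runs the greedy optimizer once per seed `0 .. nSeeds-1` and returns
#' the partition with minimal codelength (ties broken by lowest seed)
#' together with the full ensemble, which downstream boundary-persistence
#' analysis consumes.
#'
#' @param network a [TransportNetwork-class] object.
#' @param config a [MapEqConfig-class] object.
#' @return list with elements `best` (a [Partition-class]) and `ensemble`
#'   (list of [Partition-class], one per seed).
#' @export
ensembleDetect <- function(network, config = MapEqConfig()) {
  nf <- computeNodeFlow(network, config@tau)
  ens <- lapply(seq_len(config@nSeeds) - 1L, function(s) {
    optimizePartition(nf, config, seed = s)
  })
  Ls <- vapply(ens, codelength, numeric(1L))
  best <- ens[[which.min(Ls)]]   # which.min takes the first (lowest seed)
  list(best = best, ensemble = ens)
}

## restricted-growth-string enumeration of all set partitions of n items
.setPartitions <- function(n) {
  out <- list()
  a <- integer(n); a[1L] <- 1L
  recurse <- function(i, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a[seq_len(n)]
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) {
      a[i] <<- v
      recurse(i + 1L, max(mx, v))
    }
  }
  recurse(2L, 1L)
  if (n == 1L) out <- list(1L)
  out
}

#' Exhaustive map-equation optimum for small networks
#'
#' Enumerates every set partition (Bell-number enumeration) and returns
#' the global codelength minimum.  A verification oracle for the greedy
#' optimizer; limited to small node counts.
#'
#' @param nodeFlow a [NodeFlow-class] object.
#' @param markovTime Markov time.
#' @param maxNodes refuse networks larger than this (default 10).
#' @return a [Partition-class] with the globally optimal membership.
#' @export
bruteForcePartition <- function(nodeFlow, markovTime = 1, maxNodes = 10L) {
  n <- length(nodeFlow@p)
  if (n > maxNodes) stop("too many nodes for exhaustive search")
  parts <- .setPartitions(n)
  best <- NULL
  bestL <- Inf
  for (m in parts) {
    L <- mapEquation(nodeFlow, m, markovTime)
    if (L < bestL - 1e-15) {
      bestL <- L
      best <- m
    }
  }
  new("Partition", membership = stats::setNames(best, nodeFlow@nodes),
      codelength = bestL, markovTime = markovTime, seed = NA_integer_)
}

#' Write a partition
#'
#' CSV (`cell_id`, `community_id`) and a `.clu`-style listing (community
#' id per node, in node order).
#'
#' @param partition a [Partition-class] object.
#' @param file output path.
#' @export
writePartitionCSV <- function(partition, file) {
  m <- partition@membership
  utils::write.csv(data.frame(cell_id = names(m), community_id = as.integer(m)),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePartitionCSV
#' @export
writeClu <- function(partition, file) {
  m <- partition@membership
  writeLines(c(sprintf("*Vertices %d", length(m)), as.character(m)), file)
  invisible(file)
}
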