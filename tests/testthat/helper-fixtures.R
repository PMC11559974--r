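# Shared fixtures and independent oracles, all generated in code.

# minimal all-water gridded+analytic fields over a given lon/lat box;
# analytic u/v/K are functions of (lon, lat, z, t) in m/s and m^2/s
analyticFields <- function(uFun = NULL, vFun = NULL, kFun = NULL,
                           dKdxFun = NULL, dKdyFun = NULL,
                           lonRange = c(-64, -62), latRange = c(44, 46),
                           n = 5L, depths = c(1, 50), k0 = 0) {
  lonAxis <- seq(lonRange[1], lonRange[2], length.out = n)
  latAxis <- seq(latRange[1], latRange[2], length.out = n)
  nz <- length(depths)
  zero4 <- array(0, c(n, n, nz, 1L))
  an <- list()
  if (!is.null(uFun)) an$u <- uFun
  if (!is.null(vFun)) an$v <- vFun
  if (!is.null(kFun)) an$K <- kFun
  if (!is.null(dKdxFun)) an$dKdx <- dKdxFun
  if (!is.null(dKdyFun)) an$dKdy <- dKdyFun
  if (is.null(an$u)) an$u <- function(lon, lat, z, t) rep(0, length(lon))
  if (is.null(an$v)) an$v <- function(lon, lat, z, t) rep(0, length(lon))
  EnvironmentFields(lonAxis = lonAxis, latAxis = latAxis,
                    depthAxis = depths, timeDays = numeric(0),
                    u = zero4, v = zero4,
                    K = array(k0, c(n, n, nz, 1L)),
                    mld = array(20, c(n, n, 1L)),
                    bathy = matrix(100, n, n),
                    landMask = matrix(FALSE, n, n),
                    analytic = an)
}

# independent naive two-level codelength, written from the entropy
# definition rather than the plogp identity used by the package
naiveCodelength <- function(nodeFlow, memb, t = 1) {
  H <- function(x) {
    x <- x[x > 0]
    if (!length(x)) return(0)
    p <- x / sum(x)
    -sum(p * log2(p))
  }
  e <- nodeFlow@edges
  p <- nodeFlow@p
  mods <- sort(unique(memb))
  enter <- vapply(mods, function(M) {
    sel <- memb[e$from] != M & memb[e$to] == M
    t * sum(e$flow[sel])
  }, numeric(1))
  exitf <- vapply(mods, function(M) {
    sel <- memb[e$from] == M & memb[e$to] != M
    t * sum(e$flow[sel])
  }, numeric(1))
  q <- sum(enter)
  L <- if (q > 0) q * H(enter) else 0
  for (k in seq_along(mods)) {
    members <- which(memb == mods[k])
    pm <- sum(p[members]) + exitf[k]
    L <- L + pm * H(c(p[members], exitf[k]))
  }
  L
}

# seeded random row-stochastic network on n nodes
randomNetwork <- function(n, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(2:4, 1)
    data.frame(from = nodes[i], to = nodes[sample(n, k)],
               count = sample(1:9, k, replace = TRUE))
  }))
  agg <- stats::aggregate(count ~ from + to, edges, sum)
  tot <- tapply(agg$count, agg$from, sum)
  agg$prob <- agg$count / as.numeric(tot[agg$from])
  agg <- agg[order(agg$from, agg$to), ]
  new("TransportNetwork", nodes = nodes, edges = agg,
      case = "NA", resolution = 5L)
}

# planted 4-block flow map: 16 nodes, within-block probability split
# evenly over the block (self included), remainder spread evenly outside
plantedFlowMap <- function(nParticles = 10000L, within = 0.9, seed = 42L) {
  set.seed(seed)
  nodes <- sprintf("b%02d", 1:16)
  blocks <- rep(1:4, each = 4L)
  spawn <- rep(nodes, length.out = nParticles)
  b <- blocks[match(spawn, nodes)]
  inBlock <- stats::runif(nParticles) < within
  settle <- character(nParticles)
  for (i in seq_len(nParticles)) {
    settle[i] <- if (inBlock[i]) sample(nodes[blocks == b[i]], 1L)
    else sample(nodes[blocks != b[i]], 1L)
  }
  list(flowMap = flowMapFromPairs(spawn, settle), blocks = blocks,
       nodes = nodes)
}

# partitions agree up to community relabeling
samePartition <- function(m1, m2) {
  m1 <- m1[sort(names(m1))]
  m2 <- m2[sort(names(m2))]
  length(unique(paste(m1, m2))) == length(unique(m1)) &&
    length(unique(m1)) == length(unique(m2))
}

# one shared two-gyre preferred-depth run (45-day PLD), built lazily and
# reused across test files to keep the suite fast
.sharedRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fields <- makeMldAndBathy(makeDoubleGyre())
      sc <- SimConfig(seedDensity = 1500 / 313600, gridRes = 4L, rngSeed = 7L)
      sim <- runSimulation(
        seedCohort(fields, sc, BehaviorConfig(mode = "preferred_depth")),
        fields)
      habitat <- makeHabitatPatches(fields, resolution = 4L, nLineages = 3L,
                                    patchCells = 15L, rngSeed = 3L)
      pd <- resolveSettlement(sim, "PD")
      fm <- pruneToClosed(buildFlowMap(pd))
      net <- asTransportNetwork(fm)
      cache <<- list(fields = fields, simConfig = sc, sim = sim,
                     habitat = habitat, pd = pd, flowMap = fm, net = net)
    }
    cache
  }
})
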