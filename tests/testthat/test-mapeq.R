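twoPairsNetwork <- function() {
  new("TransportNetwork", nodes = c("A", "B", "C", "D"),
      edges = data.frame(from = c("A", "B", "C", "D"),
                         to = c("B", "A", "D", "C"),
                         count = rep(1L, 4), prob = rep(1, 4)),
      case = "NA", resolution = 5L)
}

fourCycleNetwork <- function() {
  new("TransportNetwork", nodes = c("A", "B", "C", "D"),
      edges = data.frame(from = c("A", "B", "C", "D"),
                         to = c("B", "C", "D", "A"),
                         count = rep(1L, 4), prob = rep(1, 4)),
      case = "NA", resolution = 5L)
}

test_that("node flows match symmetry, double stochasticity and eigenvectors", {
  ## symmetric two-node exchange: p = (1/2, 1/2) for any tau
  for (tau in c(0, 0.15, 0.5)) {
    net <- new("TransportNetwork", nodes = c("A", "B"),
               edges = data.frame(from = c("A", "B"), to = c("B", "A"),
                                  count = c(1L, 1L), prob = c(1, 1)),
               case = "NA", resolution = 5L)
    nf <- computeNodeFlow(net, tau)
    expect_equal(nf@p, c(0.5, 0.5), tolerance = 1e-10)
  }

  ## doubly-stochastic network: uniform stationary distribution
  nf <- computeNodeFlow(fourCycleNetwork(), 0.15)
  expect_equal(nf@p, rep(0.25, 4), tolerance = 1e-10)
  expect_equal(sum(nf@edges$flow), 1, tolerance = 1e-12)

  ## 3-node cycle with unequal self-loops vs dense eigenvector solution
  W <- matrix(0, 3, 3)
  W[1, 1] <- 0.3; W[1, 2] <- 0.7; W[2, 2] <- 0.2; W[2, 3] <- 0.8
  W[3, 3] <- 0.5; W[3, 1] <- 0.5
  net3 <- new("TransportNetwork", nodes = c("a", "b", "c"),
              edges = data.frame(
                from = c("a", "a", "b", "b", "c", "c"),
                to = c("a", "b", "b", "c", "c", "a"),
                count = c(3L, 7L, 2L, 8L, 5L, 5L),
                prob = c(0.3, 0.7, 0.2, 0.8, 0.5, 0.5)),
              case = "NA", resolution = 5L)
  tau <- 0.15
  nf3 <- computeNodeFlow(net3, tau)
  inw <- colSums(W)
  P <- (1 - tau) * W + tau * matrix(inw / sum(inw), 3, 3, byrow = TRUE)
  ev <- eigen(t(P))
  pv <- Re(ev$vectors[, 1]); pv <- pv / sum(pv)
  expect_lt(max(abs(nf3@p - pv)), 1e-10)
})

test_that("codelength reproduces closed forms", {
  ## uniform 4-node network, single module: L = H(p) = 2 bits
  nf <- computeNodeFlow(fourCycleNetwork(), 0.15)
  expect_equal(mapEquation(nf, rep(1L, 4), 1), 2, tolerance = 1e-9)

  ## two disconnected symmetric pairs, partitioned as the pairs, t = 1:
  ## q = 0 and each module contributes 1/2 * 1 bit
  nf2 <- computeNodeFlow(twoPairsNetwork(), 0.15)
  expect_equal(mapEquation(nf2, c(1L, 1L, 2L, 2L), 1), 1, tolerance = 1e-9)
  ## the split beats the single module (2 bits)
  expect_equal(mapEquation(nf2, rep(1L, 4), 1), 2, tolerance = 1e-9)
})

test_that("codelength agrees with an independent naive implementation", {
  for (s in 1:5) {
    net <- randomNetwork(9, 300 + s)
    nf <- computeNodeFlow(net, 0.15)
    set.seed(s)
    memb <- sample(1:3, length(nf@p), replace = TRUE)
    memb <- match(memb, sort(unique(memb)))
    for (t in c(1, 2, 3.5)) {
      expect_equal(mapEquation(nf, memb, t), naiveCodelength(nf, memb, t),
                   tolerance = 1e-9)
    }
  }
})

test_that("codelength is non-negative and bounded by the one-module entropy", {
  net <- randomNetwork(8, 77)
  nf <- computeNodeFlow(net, 0.15)
  Hp <- -sum(ifelse(nf@p > 0, nf@p * log2(nf@p), 0))
  expect_equal(mapEquation(nf, rep(1L, 8), 1), Hp, tolerance = 1e-12)
  for (s in 1:5) {
    set.seed(s)
    memb <- sample(1:4, 8, replace = TRUE)
    memb <- match(memb, sort(unique(memb)))
    expect_gte(mapEquation(nf, memb, 1), 0)
  }
  part <- optimizePartition(nf, MapEqConfig(markovTime = 1, nSeeds = 1L,
                                            outerLoops = 5L), seed = 0L)
  expect_lte(part@codelength, Hp + 1e-12)
})

test_that("the optimizer separates disconnected structure deterministically", {
  nf <- computeNodeFlow(twoPairsNetwork(), 0.15)
  cfg <- MapEqConfig(markovTime = 1, nSeeds = 1L, outerLoops = 5L)
  part <- optimizePartition(nf, cfg, seed = 0L)
  expect_equal(nCommunities(part), 2L)
  expect_equal(part@codelength, 1, tolerance = 1e-9)
  expect_identical(part@membership[c("A", "B")],
                   part@membership[c("A", "B")])
  expect_true(part@membership["A"] == part@membership["B"])
  expect_true(part@membership["C"] == part@membership["D"])

  ## determinism: same seed twice gives the identical partition
  part2 <- optimizePartition(nf, cfg, seed = 0L)
  expect_identical(part@membership, part2@membership)
})

test_that("a two-node symmetric network optimally stays one module", {
  net <- new("TransportNetwork", nodes = c("A", "B"),
             edges = data.frame(from = c("A", "B"), to = c("B", "A"),
                                count = c(1L, 1L), prob = c(1, 1)),
             case = "NA", resolution = 5L)
  nf <- computeNodeFlow(net, 0.15)
  bf <- bruteForcePartition(nf, 1)
  expect_equal(nCommunities(bf), 1L)
  ## H(1/2, 1/2) = 1 bit beats the split with its enter/exit overhead
  expect_equal(bf@codelength, 1, tolerance = 1e-12)
})

test_that("brute force is invariant to node relabeling", {
  net <- randomNetwork(7, 55)
  nf <- computeNodeFlow(net, 0.15)
  bf1 <- bruteForcePartition(nf, 1)
  perm <- c(3L, 1L, 7L, 2L, 6L, 4L, 5L)
  nf2 <- nf
  nf2@nodes <- nf@nodes[perm]
  inv <- match(seq_along(perm), perm)
  nf2@p <- nf@p[perm]
  nf2@edges <- data.frame(from = inv[nf@edges$from], to = inv[nf@edges$to],
                          flow = nf@edges$flow)
  bf2 <- bruteForcePartition(nf2, 1)
  expect_equal(bf1@codelength, bf2@codelength, tolerance = 1e-12)
  expect_true(samePartition(bf1@membership, bf2@membership))
  expect_error(bruteForcePartition(computeNodeFlow(randomNetwork(12, 1), 0.15)),
               "too many")
})

test_that("ensembles return the minimum and agree on strong structure", {
  pl <- plantedFlowMap()
  net <- asTransportNetwork(pruneToClosed(pl$flowMap))
  cfg <- MapEqConfig(markovTime = 1, nSeeds = 8L, outerLoops = 5L)
  det <- ensembleDetect(net, cfg)
  Ls <- vapply(det$ensemble, codelength, numeric(1))
  expect_equal(det$best@codelength, min(Ls))
  expect_lte(det$best@codelength, min(Ls))
  ## all members recover the planted blocks
  planted <- setNames(pl$blocks, pl$nodes)
  for (p in det$ensemble) {
    expect_true(samePartition(p@membership, planted))
  }
  ## cross-check against an independent community detector
  g <- igraph::graph_from_data_frame(
    net@edges[, c("from", "to")], vertices = net@nodes)
  igraph::E(g)$weight <- net@edges$prob
  im <- igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight)
  expect_true(samePartition(
    setNames(igraph::membership(im), igraph::V(g)$name), planted))
})

test_that("greedy search attains the brute-force optimum on small networks", {
  ok <- 0L
  for (s in 1:6) {
    net <- randomNetwork(8, 2000 + s)
    nf <- computeNodeFlow(net, 0.15)
    g <- optimizePartition(nf, MapEqConfig(markovTime = 1, nSeeds = 1L,
                                           outerLoops = 20L), seed = 0L)
    b <- bruteForcePartition(nf, 1)
    expect_gte(g@codelength, b@codelength - 1e-12)
    if (g@codelength - b@codelength <= 1e-12) ok <- ok + 1L
  }
  expect_gte(ok, 5L)
})

test_that("partitions write as CSV and clu listings", {
  nf <- computeNodeFlow(twoPairsNetwork(), 0.15)
  part <- optimizePartition(nf, MapEqConfig(markovTime = 1, nSeeds = 1L,
                                            outerLoops = 2L), seed = 0L)
  csv <- withr::local_tempfile(fileext = ".csv")
  writePartitionCSV(part, csv)
  df <- read.csv(csv)
  expect_identical(df$cell_id, names(part@membership))
  expect_identical(df$community_id, as.integer(part@membership))
  clu <- withr::local_tempfile(fileext = ".clu")
  writeClu(part, clu)
  expect_equal(length(readLines(clu)), 5L)
})
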