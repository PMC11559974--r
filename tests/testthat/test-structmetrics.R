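# a small hand-built flow map over 6 cells in two communities:
#   community 1 = {a, b}, community 2 = {c, d}
toyAssigned <- function() {
  spawn  <- c("a", "a", "a", "b", "b", "c", "c", "d", "d", "d")
  settle <- c("a", "b", "c", "b", "a", "c", "d", "d", "c", "a")
  fm <- flowMapFromPairs(spawn, settle)
  m <- setNames(c(1L, 1L, 2L, 2L), c("a", "b", "c", "d"))
  list(fm = fm, m = m)
}

test_that("coherence and fortress ratios are direct count fractions", {
  toy <- toyAssigned()
  rho <- coherenceRatio(toy$fm, toy$m)
  fort <- fortressRatio(toy$fm, toy$m)
  ## community 1 spawns 5, retains 4 (a->c leaves)
  expect_equal(as.numeric(rho["1"]), 4 / 5)
  ## community 2 spawns 5, retains 4 (d->a leaves)
  expect_equal(as.numeric(rho["2"]), 4 / 5)
  ## community 1 receives 5 settlers, 4 internal
  expect_equal(as.numeric(fort["1"]), 4 / 5)
  ## complement: 1 - F = fraction of settlers spawned elsewhere
  counts <- table(toy$m[toy$fm@pairs$spawnCell], toy$m[toy$fm@pairs$settleCell])
  external <- counts[2, 1] / sum(counts[, 1])
  expect_equal(1 - fort[["1"]], as.numeric(external))

  ## all-internal and all-external extremes
  fmAll <- flowMapFromPairs(c("a", "b"), c("b", "a"))
  mAll <- setNames(c(1L, 1L), c("a", "b"))
  expect_equal(as.numeric(coherenceRatio(fmAll, mAll)), 1)
  expect_equal(as.numeric(fortressRatio(fmAll, mAll)), 1)
  fmOut <- flowMapFromPairs(c("a", "b"), c("b", "a"))
  mOut <- setNames(c(1L, 2L), c("a", "b"))
  expect_equal(as.numeric(coherenceRatio(fmOut, mOut)), c(0, 0))
  ## worked fractions: 10 spawned, 4 retained -> 0.4; 20 settled, 5 internal -> 0.25
  fmW <- flowMapFromPairs(c(rep("a", 10), rep("b", 16)),
                          c(rep("a", 4), rep("b", 6), rep("a", 15), "b"))
  mW <- setNames(c(1L, 2L), c("a", "b"))
  expect_equal(as.numeric(coherenceRatio(fmW, mW)["1"]), 0.4)
  expect_equal(as.numeric(fortressRatio(fmW, mW)["1"]), 4 / 19)

  expect_error(coherenceRatio(toy$fm, setNames(1L, "a")), "assigned")
})

test_that("ratios are invariant to relabeling and particle order", {
  run <- .sharedRun()
  det <- optimizePartition(computeNodeFlow(run$net, 0.15),
                           MapEqConfig(markovTime = 2, nSeeds = 1L,
                                       outerLoops = 3L), seed = 0L)
  m <- det@membership
  rho1 <- coherenceRatio(run$flowMap, m)
  ## relabel communities in reverse
  k <- max(m)
  m2 <- setNames(k + 1L - m, names(m))
  rho2 <- coherenceRatio(run$flowMap, m2)
  expect_equal(as.numeric(rho1), rev(as.numeric(rho2)))
  ## shuffle particles
  fmS <- run$flowMap
  set.seed(1)
  fmS@pairs <- fmS@pairs[sample(nrow(fmS@pairs)), ]
  expect_equal(coherenceRatio(fmS, m), rho1)
})

test_that("mixing parameter matches its closed forms", {
  mkNet <- function(edges) {
    nodes <- sort(unique(c(edges$from, edges$to)))
    tot <- tapply(edges$prob, edges$from, sum)
    stopifnot(all(abs(tot - 1) < 1e-12))
    new("TransportNetwork", nodes = nodes,
        edges = cbind(edges, count = 1L)[, c("from", "to", "count", "prob")],
        case = "NA", resolution = 5L)
  }
  m4 <- setNames(rep(1L, 4), c("a", "b", "c", "d"))

  ## each node spreads equally over all 4 community members -> 1
  uni <- expand.grid(from = c("a", "b", "c", "d"), to = c("a", "b", "c", "d"),
                     stringsAsFactors = FALSE)
  uni$prob <- 0.25
  expect_equal(as.numeric(mixingParameter(mkNet(uni), m4)), 1)

  ## deterministic internal routing -> 0
  det <- data.frame(from = c("a", "b", "c", "d"), to = c("b", "c", "d", "a"),
                    prob = 1)
  expect_equal(as.numeric(mixingParameter(mkNet(det), m4)), 0)

  ## two nodes splitting internal flow 0.8/0.2: H(0.8, 0.2) = 0.7219 bits
  two <- data.frame(from = c("a", "a", "b", "b"), to = c("a", "b", "b", "a"),
                    prob = c(0.8, 0.2, 0.8, 0.2))
  m2 <- setNames(c(1L, 1L), c("a", "b"))
  expect_equal(as.numeric(mixingParameter(mkNet(two), m2)),
               -(0.8 * log2(0.8) + 0.2 * log2(0.2)), tolerance = 1e-9)

  ## singleton community convention
  single <- data.frame(from = "a", to = "a", prob = 1)
  expect_equal(as.numeric(mixingParameter(mkNet(single),
                                          setNames(1L, "a"))), 1)
})

test_that("classification follows the source/sink-first decision rule", {
  cfg <- ClassifierConfig()
  expect_identical(classifyCommunity(1.00, 0.17, cfg), "sink")
  expect_identical(classifyCommunity(0.93, 0.98, cfg), "source")  # diff exactly 0.05
  expect_identical(classifyCommunity(0.91, 0.90, cfg), "permeable")
  expect_identical(classifyCommunity(0.97, 0.95, cfg), "impermeable")  # >= h
  expect_identical(classifyCommunity(0.98, 0.81, cfg), "sink")
  expect_identical(classifyCommunity(1.00, 1.00, cfg), "impermeable")
  ## residual straddle: one high, one low, difference under delta
  expect_identical(classifyCommunity(0.96, 0.93, cfg), "unclassified")
  expect_error(classifyCommunity(1.2, 0.5, cfg), "0, 1")
})

test_that("the full reference table of quality classifications is reproduced", {
  ref <- read.csv(system.file("extdata", "classification_reference.csv",
                              package = "larvanet"))
  got <- classifyCommunity(ref$coherence, ref$fortress, ClassifierConfig())
  expect_identical(got, ref$classification)
  expect_equal(as.integer(table(got)[c("sink", "source", "permeable",
                                       "impermeable")]), c(3L, 4L, 1L, 7L))
})

test_that("global quality is a bin-weighted mean with conservation identities", {
  q <- data.frame(community = 1:3, nBins = c(2L, 2L, 2L),
                  mixing = c(0.2, 0.4, 0.6), coherence = c(1, 0.5, 0.9),
                  fortress = c(0.8, 0.7, 0.6),
                  classification = "permeable")
  g <- globalQuality(q)
  expect_equal(as.numeric(g["mixing"]), mean(q$mixing))
  q2 <- q[1, ]
  expect_equal(as.numeric(globalQuality(q2)), c(0.2, 1, 0.8))

  ## particle-weighted global coherence equals particle-weighted global
  ## fortress exactly: every retained particle spawns and settles once
  run <- .sharedRun()
  det <- optimizePartition(computeNodeFlow(run$net, 0.15),
                           MapEqConfig(markovTime = 2, nSeeds = 1L,
                                       outerLoops = 3L), seed = 0L)
  counts <- larvanet:::.communityCounts(run$flowMap, det@membership)
  spawned <- rowSums(counts); settled <- colSums(counts)
  expect_equal(sum(spawned), sum(settled))
  expect_equal(sum(spawned), nrow(run$flowMap@pairs))
  ## spawn-weighted coherence and settle-weighted fortress both reduce to
  ## retained / total (zero-settler communities contribute zero weight)
  wRho <- sum(spawned / sum(spawned) * diag(counts) / spawned)
  wFort <- sum(ifelse(settled > 0,
                      settled / sum(settled) * diag(counts) / pmax(settled, 1),
                      0))
  expect_equal(wRho, wFort)
})

test_that("connectivity matrices are row-stochastic with coherence diagonal", {
  toy <- toyAssigned()
  cm <- connectivityMatrix(toy$fm, toy$m)
  expect_equal(rowSums(cm), c("1" = 1, "2" = 1))
  expect_identical(unname(diag(cm)),
                   as.numeric(coherenceRatio(toy$fm, toy$m)))

  ## worked proportion: 100 spawned in a, 7 settling in b -> entry 0.07
  fmP <- flowMapFromPairs(c(rep("a", 100), "b"),
                          c(rep("a", 93), rep("b", 7), "b"))
  mP <- setNames(c(1L, 2L), c("a", "b"))
  cmP <- connectivityMatrix(fmP, mP)
  expect_equal(cmP["1", "2"], 0.07)

  ## no exchange -> identity matrix
  fmI <- flowMapFromPairs(c("a", "b"), c("a", "b"))
  expect_equal(connectivityMatrix(fmI, mP), diag(2),
               ignore_attr = TRUE)

  run <- .sharedRun()
  det <- optimizePartition(computeNodeFlow(run$net, 0.15),
                           MapEqConfig(markovTime = 2, nSeeds = 1L,
                                       outerLoops = 3L), seed = 0L)
  cmR <- connectivityMatrix(run$flowMap, det@membership)
  expect_true(all(abs(rowSums(cmR) - 1) < 1e-12))
  expect_identical(unname(diag(cmR)),
                   as.numeric(coherenceRatio(run$flowMap, det@membership)))
})

test_that("boundary persistence counts adjacency disagreements", {
  ## synthetic 1-d chain of cells with a known adjacency
  cells <- sprintf("c%d", 1:5)
  nbrs <- list(c1 = "c2", c2 = c("c1", "c3"), c3 = c("c2", "c4"),
               c4 = c("c3", "c5"), c5 = "c4")
  mkPart <- function(m) new("Partition", membership = setNames(m, cells),
                            codelength = 0, markovTime = 1, seed = 0L)
  ## identical partitions: persistence is 0 or 1
  ensA <- replicate(4, mkPart(c(1L, 1L, 1L, 2L, 2L)), simplify = FALSE)
  bp <- boundaryPersistence(ensA, neighbors = nbrs)
  expect_true(all(bp %in% c(0, 1)))
  expect_equal(bp[["c3"]], 1)  # adjacent to c4 in the other community
  expect_equal(bp[["c1"]], 0)  # interior in every solution

  ## 10-member ensemble, boundary in 7 -> 0.7
  ens <- c(replicate(7, mkPart(c(1L, 1L, 1L, 2L, 2L)), simplify = FALSE),
           replicate(3, mkPart(c(1L, 1L, 1L, 1L, 1L)), simplify = FALSE))
  bp <- boundaryPersistence(ens, neighbors = nbrs)
  expect_equal(bp[["c3"]], 0.7)
  expect_equal(bp[["c1"]], 0)

  ## inconsistent cell sets are rejected
  bad <- mkPart(c(1L, 1L, 1L, 2L, 2L))
  names(bad@membership)[1] <- "zz"
  expect_error(boundaryPersistence(list(ensA[[1]], bad), neighbors = nbrs),
               "cell sets")
})
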