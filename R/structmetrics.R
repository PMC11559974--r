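## Community quality metrics for a partitioned transport network.
##
## Coherence ratio: fraction of a community's spawned particles that
## settle inside it (outward border strength, local retention).
## Fortress ratio: fraction of a community's settlers that also spawned
## inside it (inward border strength, self-recruitment).  Mixing
## parameter: how uniformly particles spread from each bin of a
## community over that community's bins.  Coherence and fortress jointly
## classify communities as sink / source / permeable / impermeable.

## community-by-community transition count matrix from a flow map
.communityCounts <- function(flowMap, partition) {
  m <- if (methods::is(partition, "Partition")) partition@membership else partition
  pairs <- flowMap@pairs
  if (!all(pairs$spawnCell %in% names(m)) ||
      !all(pairs$settleCell %in% names(m))) {
    stop("every flow-map cell must be assigned a community")
  }
  k <- max(m)
  cs <- m[pairs$spawnCell]
  ct <- m[pairs$settleCell]
  counts <- matrix(0L, k, k, dimnames = list(seq_len(k), seq_len(k)))
  tab <- table(factor(cs, levels = seq_len(k)), factor(ct, levels = seq_len(k)))
  counts[] <- as.integer(tab)
  counts
}

#' Coherence and fortress ratios
#'
#' `coherenceRatio`: per community, retained spawners / total spawners --
#' 1 when every particle spawned in the community also settled there, 0
#' when all left.  `fortressRatio`: per community, internally-spawned
#' settlers / total settlers -- its complement is the fraction of a
#' community's settlers that immigrated.  A community that receives no
#' settlers has an undefined fortress ratio, reported as `NA` with a
#' warning (cannot occur after pruning when every node spawns into the
#' network, but guarded).
#'
#' @param flowMap a [FlowMap-class] whose cells are all assigned.
#' @param partition a [Partition-class] or named membership vector.
#' @return numeric vector of per-community ratios (names = community id).
#' @export
coherenceRatio <- function(flowMap, partition) {
  counts <- .communityCounts(flowMap, partition)
  spawned <- rowSums(counts)
  out <- diag(counts) / spawned
  stats::setNames(out, rownames(counts))
}

#' @rdname coherenceRatio
#' @export
fortressRatio <- function(flowMap, partition) {
  counts <- .communityCounts(flowMap, partition)
  settled <- colSums(counts)
  out <- diag(counts) / settled
  if (any(settled == 0)) {
    warning("community with zero settlers: fortress ratio undefined (NA)")
    out[settled == 0] <- NA_real_
  }
  stats::setNames(out, colnames(counts))
}

#' Mixing parameter
#'
#' Mean over a community's member nodes of the base-2 entropy of the
#' node's within-community transition distribution (renormalized over
#' community members, self-loops included), divided by `log2(n_c)`.
#' Unity means particles disperse from each bin to every bin of the
#' community in equal quantities; zero means each bin routes all its
#' internal flow to a single bin.  Singleton communities return 1 by
#' convention; a member with no internal flow contributes 0.
#'
#' @param network a [TransportNetwork-class] object.
#' @param partition a [Partition-class] or named membership vector.
#' @return numeric vector of per-community mixing values in `[0, 1]`.
#' @export
mixingParameter <- function(network, partition) {
  m <- if (methods::is(partition, "Partition")) partition@membership else partition
  if (!all(network@nodes %in% names(m))) stop("unassigned nodes")
  k <- max(m)
  e <- network@edges
  mf <- m[e$from]; mt <- m[e$to]
  out <- numeric(k)
  for (comm in seq_len(k)) {
    members <- network@nodes[m[network@nodes] == comm]
    nc <- length(members)
    if (nc == 1L) { out[comm] <- 1; next }
    internal <- e[mf == comm & mt == comm, , drop = FALSE]
    hs <- vapply(members, function(nd) {
      w <- internal$prob[internal$from == nd]
      if (!length(w) || sum(w) <= 0) return(0)
      q <- w / sum(w)
      -sum(.plogp(q))
    }, numeric(1L))
    out[comm] <- mean(hs) / log2(nc)
  }
  stats::setNames(out, seq_len(k))
}

#' Classify communities from coherence and fortress ratios
#'
#' Decision rule with thresholds from [ClassifierConfig()]: a community
#' is a `sink` if coherence exceeds fortress by at least `delta`, a
#' `source` if fortress exceeds coherence by at least `delta`; otherwise
#' `impermeable` if both ratios are at least `h`, `permeable` if both are
#' below `h`, and `unclassified` in the residual straddle case.
#'
#' @param coherence,fortress numeric vectors in `[0, 1]` (recycled to a
#'   common length).
#' @param config a [ClassifierConfig-class] object.
#' @return character vector of labels.
#' @export
classifyCommunity <- function(coherence, fortress, config = ClassifierConfig()) {
  if (any(coherence < 0 | coherence > 1, na.rm = TRUE) ||
      any(fortress < 0 | fortress > 1, na.rm = TRUE)) {
    stop("ratios must lie in [0, 1]")
  }
  n <- max(length(coherence), length(fortress))
  coherence <- rep_len(coherence, n)
  fortress <- rep_len(fortress, n)
  ## threshold comparisons at printed (two-decimal) precision must not
  ## fail to round-off, e.g. 0.98 - 0.93 underflows 0.05 in doubles
  eps <- 1e-9
  out <- rep("unclassified", n)
  out[which(coherence - fortress >= config@delta - eps)] <- "sink"
  out[which(fortress - coherence >= config@delta - eps)] <- "source"
  rest <- out == "unclassified"
  out[which(rest & pmin(coherence, fortress) >= config@h - eps)] <- "impermeable"
  out[which(rest & pmax(coherence, fortress) < config@h - eps)] <- "permeable"
  out[which(is.na(coherence) | is.na(fortress))] <- "unclassified"
  out
}

#' Community quality table
#'
#' Assembles per-community size, mixing, coherence, fortress and
#' classification into one data.frame (community ids in ascending
#' order), mirroring the layout of a community quality table.
#'
#' @param network a [TransportNetwork-class] object.
#' @param flowMap the [FlowMap-class] the network was built from.
#' @param partition a [Partition-class] or named membership vector.
#' @param config a [ClassifierConfig-class] object.
#' @return data.frame with columns `community`, `nBins`, `mixing`,
#'   `coherence`, `fortress`, `classification`.
#' @export
communityQuality <- function(network, flowMap, partition,
                             config = ClassifierConfig()) {
  m <- if (methods::is(partition, "Partition")) partition@membership else partition
  rho <- coherenceRatio(flowMap, partition)
  fort <- fortressRatio(flowMap, partition)
  mix <- mixingParameter(network, partition)
  nBins <- as.integer(table(factor(m, levels = seq_len(max(m)))))
  data.frame(community = seq_len(max(m)), nBins = nBins,
             mixing = as.numeric(mix), coherence = as.numeric(rho),
             fortress = as.numeric(fort),
             classification = classifyCommunity(rho, fort, config),
             stringsAsFactors = FALSE)
}

#' Global partition quality
#'
#' Community quality metrics averaged over communities weighted by the
#' number of bins in each, summarizing the quality of the whole network
#' partition.
#'
#' @param quality a data.frame from [communityQuality()].
#' @return named numeric vector `mixing`, `coherence`, `fortress`.
#' @export
globalQuality <- function(quality) {
  w <- quality$nBins / sum(quality$nBins)
  c(mixing = sum(w * quality$mixing),
    coherence = sum(w * quality$coherence),
    fortress = sum(w * quality$fortress, na.rm = any(is.na(quality$fortress))))
}

#' Community connectivity matrix
#'
#' Row-stochastic matrix of transition proportions between communities:
#' entry (a, b) is the fraction of community a's spawned particles that
#' settled in community b.  The main diagonal is identical (bit-exact,
#' same integer-count arithmetic) to the coherence ratio.
#'
#' @param flowMap a [FlowMap-class] whose cells are all assigned.
#' @param partition a [Partition-class] or named membership vector.
#' @return numeric matrix with community ids as dimnames.
#' @export
connectivityMatrix <- function(flowMap, partition) {
  counts <- .communityCounts(flowMap, partition)
  counts / rowSums(counts)
}

#' Boundary persistence over a partition ensemble
#'
#' A bin is a boundary bin in one partition if it is directly adjacent
#' (grid adjacency) to at least one bin belonging to a different
#' community than its own.  The boundary persistence of a bin is the
#' fraction of ensemble partitions in which it is a boundary bin.
#' Neighbors absent from the network are ignored.
#'
#' @param partitionEnsemble list of [Partition-class] objects covering
#'   the same cell set.
#' @param neighbors optional named list cell -> neighboring cells; looked
#'   up with [cellNeighbors()] when omitted.
#' @return named numeric vector: per-cell boundary persistence in `[0, 1]`.
#' @export
boundaryPersistence <- function(partitionEnsemble, neighbors = NULL) {
  cells <- sort(names(partitionEnsemble[[1L]]@membership))
  for (p in partitionEnsemble) {
    if (!identical(sort(names(p@membership)), cells)) {
      stop("ensemble partitions cover different cell sets")
    }
  }
  if (is.null(neighbors)) {
    neighbors <- lapply(cells, function(cc) intersect(cellNeighbors(cc), cells))
    names(neighbors) <- cells
  } else {
    neighbors <- lapply(neighbors[cells], intersect, y = cells)
  }
  hits <- stats::setNames(numeric(length(cells)), cells)
  for (p in partitionEnsemble) {
    m <- p@membership
    isBoundary <- vapply(cells, function(cc) {
      nb <- neighbors[[cc]]
      length(nb) > 0L && any(m[nb] != m[cc])
    }, logical(1L))
    hits <- hits + isBoundary
  }
  hits / length(partitionEnsemble)
}

#' Write community quality outputs
#'
#' Quality table, connectivity matrix and boundary persistence as CSV.
#'
#' @param quality data.frame from [communityQuality()].
#' @param file output path.
#' @export
writeQualityCSV <- function(quality, file) {
  utils::write.csv(quality, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeQualityCSV
#' @param mat matrix from [connectivityMatrix()].
#' @export
writeConnectivityCSV <- function(mat, file) {
  utils::write.csv(data.frame(community = rownames(mat), mat,
                              check.names = FALSE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writeQualityCSV
#' @param persistence named vector from [boundaryPersistence()].
#' @export
writeBoundaryCSV <- function(persistence, file) {
  utils::write.csv(data.frame(cell_id = names(persistence),
                              fraction = as.numeric(persistence)),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
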