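## From trajectories to a Markov-chain-like transport network: each
## surviving particle contributes a single spawn-bin -> settlement-bin
## transition (the flow map); transitions are pruned so every settle
## cell is also a spawn cell, then normalized per spawn cell into
## transition probabilities.

#' Build the flow map of a resolved cohort
#'
#' One (spawn cell, settle cell) pair per settled particle.  Intermediate
#' bins traversed between spawn and settlement are not retained: the flow
#' map is the only particle movement downstream analyses can reference.
#'
#' @param cohort a [ParticleCohort-class] with settlement resolved.
#' @return a [FlowMap-class] object.
#' @export
buildFlowMap <- function(cohort) {
  if (!nzchar(cohort@case)) stop("settlement not resolved; run resolveSettlement")
  p <- cohort@particles
  s <- p$status == "settled"
  new("FlowMap",
      pairs = data.frame(id = p$id[s], spawnCell = p$spawnCell[s],
                         settleCell = p$settleCell[s],
                         stringsAsFactors = FALSE),
      case = cohort@case, resolution = cohort@simConfig@gridRes)
}

#' Flow map from explicit pairs
#'
#' Convenience constructor for analyses starting from a transition table
#' rather than a simulated cohort.
#'
#' @param spawnCell,settleCell character vectors of equal length.
#' @param case label (default "NA").
#' @param resolution grid resolution of the ids (default 5).
#' @return a [FlowMap-class] object.
#' @export
flowMapFromPairs <- function(spawnCell, settleCell, case = "NA",
                             resolution = 5L) {
  stopifnot(length(spawnCell) == length(settleCell))
  new("FlowMap",
      pairs = data.frame(id = seq_along(spawnCell),
                         spawnCell = as.character(spawnCell),
                         settleCell = as.character(settleCell),
                         stringsAsFactors = FALSE),
      case = case, resolution = as.integer(resolution))
}

#' Prune a flow map to a closed cell set
#'
#' Repeatedly deletes particles that settle in cells no surviving
#' particle spawned in, until a fixed point is reached: deleting such
#' particles can empty a spawn cell, which invalidates further particles,
#' so a single pass is not sufficient.  On return the settle-cell set is
#' a subset of the spawn-cell set, so every node of the derived network
#' has out-links and the transition matrix stays singly stochastic.  The
#' operation is idempotent.
#'
#' @param flowMap a [FlowMap-class] object.
#' @return the pruned [FlowMap-class]; warns if pruning empties the map.
#' @export
pruneToClosed <- function(flowMap) {
  pairs <- flowMap@pairs
  if (!nrow(pairs)) stop("empty flow map")
  repeat {
    spawned <- unique(pairs$spawnCell)
    keep <- pairs$settleCell %in% spawned
    if (all(keep)) break
    pairs <- pairs[keep, , drop = FALSE]
    if (!nrow(pairs)) {
      warning("pruning removed every particle; flow map is empty")
      break
    }
  }
  flowMap@pairs <- pairs
  flowMap
}

#' Transport network from a pruned flow map
#'
#' Aggregates transitions into a directed weighted network whose link
#' weight i -> j is `count(i -> j) / count(i -> .)`: the probability for
#' a particle spawning at node i to settle at node j.  Raw integer counts
#' are retained alongside.  Requires a closed (pruned) flow map so that
#' every node has out-links.
#'
#' @param flowMap a pruned [FlowMap-class] object.
#' @return a [TransportNetwork-class] object.
#' @export
asTransportNetwork <- function(flowMap) {
  pairs <- flowMap@pairs
  if (!nrow(pairs)) stop("empty flow map")
  if (!all(pairs$settleCell %in% pairs$spawnCell)) {
    stop("flow map contains dangling settle cells; apply pruneToClosed first")
  }
  nodes <- sort(unique(pairs$spawnCell))
  agg <- stats::aggregate(list(count = rep(1L, nrow(pairs))),
                          by = list(from = pairs$spawnCell,
                                    to = pairs$settleCell), FUN = sum)
  agg <- agg[order(agg$from, agg$to), , drop = FALSE]
  tot <- tapply(agg$count, agg$from, sum)
  agg$prob <- agg$count / as.numeric(tot[agg$from])
  rownames(agg) <- NULL
  new("TransportNetwork", nodes = nodes, edges = agg,
      case = flowMap@case, resolution = flowMap@resolution)
}

#' Write and read networks
#'
#' Pajek `.net` (nodes plus weighted directed arcs, weights =
#' probabilities) and a TSV edge list (`src`, `dst`, `count`, `prob`).
#'
#' @param network a [TransportNetwork-class] object.
#' @param file output path.
#' @export
writePajek <- function(network, file) {
  con <- file(file, "w")
  on.exit(close(con))
  nodes <- network@nodes
  writeLines(sprintf("*Vertices %d", length(nodes)), con)
  writeLines(sprintf("%d \"%s\"", seq_along(nodes), nodes), con)
  writeLines("*Arcs", con)
  e <- network@edges
  writeLines(sprintf("%d %d %.17g", match(e$from, nodes), match(e$to, nodes),
                     e$prob), con)
  invisible(file)
}

#' @rdname writePajek
#' @export
readPajek <- function(file) {
  lines <- readLines(file)
  nv <- as.integer(sub("\\*Vertices\\s+", "", lines[1L], ignore.case = TRUE))
  vlines <- lines[2:(nv + 1L)]
  nodes <- sub("^\\d+\\s+\"(.*)\"\\s*$", "\\1", vlines)
  arcStart <- grep("^\\*Arcs", lines, ignore.case = TRUE)[1L] + 1L
  if (is.na(arcStart) || arcStart > length(lines)) {
    stop("no arcs section")
  }
  arcs <- utils::read.table(text = lines[arcStart:length(lines)],
                            col.names = c("from", "to", "weight"))
  edges <- data.frame(from = nodes[arcs$from], to = nodes[arcs$to],
                      count = NA_integer_, prob = arcs$weight,
                      stringsAsFactors = FALSE)
  new("TransportNetwork", nodes = sort(nodes), edges = edges,
      case = "NA", resolution = NA_integer_)
}

#' @rdname writePajek
#' @export
writeEdgeList <- function(network, file) {
  e <- network@edges
  utils::write.table(
    data.frame(src = e$from, dst = e$to, count = e$count, prob = e$prob),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname writePajek
#' @export
writeFlowMapCSV <- function(flowMap, file) {
  utils::write.csv(
    data.frame(particle_id = flowMap@pairs$id,
               spawn_cell = flowMap@pairs$spawnCell,
               settle_cell = flowMap@pairs$settleCell),
    file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
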