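#' Erdos-Renyi random graph
#'
#' Each of the N(N-1)/2 unordered pairs is an edge independently with
#' probability `p`. Seed-deterministic; node labels are "1".."N".
#'
#' @param numNodes number of nodes (>= 4)
#' @param p edge probability in [0, 1]
#' @param seed optional integer seed
#' @return a [LinkNet-class]
#' @export
sampleErdosRenyi <- function(numNodes, p, seed = NULL) {
  .checkGenArgs(numNodes, p)
  n <- as.integer(numNodes)
  lab <- as.character(seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  on <- .withSeed(seed, stats::runif(nrow(pairs)) < p)
  linkNet(cbind(lab[pairs[on, 1L]], lab[pairs[on, 2L]]), nodeLabels = lab)
}

#' Planted-partition (stochastic block) random graph
#'
#' Nodes are divided into equal-size blocks; within-block pairs are
#' edges with probability `pIn`, between-block pairs with probability
#' `pOut`. With strong blocks (pIn >> pOut) removed within-block edges
#' retain many common neighbours — exactly the structure
#' common-neighbour predictors, including the walk model, exploit. The
#' defaults (120 nodes, 4 blocks, pIn 0.4, pOut 0.02) give a modular
#' graph on which the full benchmark runs in seconds.
#'
#' @param numNodes number of nodes (>= 4), divided as evenly as
#'   possible among the blocks
#' @param numBlocks number of planted blocks
#' @param pIn,pOut within/between-block edge probabilities in [0, 1]
#' @param seed optional integer seed
#' @return a [LinkNet-class]; block membership attached as attribute
#'   `"block"`
#' @export
samplePlantedPartition <- function(numNodes = 120L, numBlocks = 4L,
                                   pIn = 0.4, pOut = 0.02, seed = NULL) {
  .checkGenArgs(numNodes, c(pIn, pOut))
  n <- as.integer(numNodes)
  block <- sort(rep_len(seq_len(numBlocks), n))
  lab <- as.character(seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  prob <- ifelse(block[pairs[, 1L]] == block[pairs[, 2L]], pIn, pOut)
  on <- .withSeed(seed, stats::runif(nrow(pairs)) < prob)
  net <- linkNet(cbind(lab[pairs[on, 1L]], lab[pairs[on, 2L]]),
                 nodeLabels = lab)
  attr(net, "block") <- block
  net
}

#' Watts-Strogatz small-world random graph
#'
#' Ring lattice of `numNodes` nodes each joined to its `nei` nearest
#' neighbours on either side, with each edge rewired independently with
#' probability `rewireP`; multiples and loops are simplified away.
#'
#' @param numNodes number of nodes (>= 4)
#' @param nei lattice half-neighbourhood size
#' @param rewireP rewiring probability in [0, 1]
#' @param seed optional integer seed
#' @return a [LinkNet-class]
#' @export
sampleSmallWorld <- function(numNodes = 100L, nei = 2L, rewireP = 0.1,
                             seed = NULL) {
  .checkGenArgs(numNodes, rewireP)
  g <- .withSeed(seed,
    igraph::sample_smallworld(1, as.integer(numNodes), as.integer(nei),
                              rewireP))
  g <- igraph::simplify(g)
  e <- igraph::as_edgelist(g, names = FALSE)
  lab <- as.character(seq_len(as.integer(numNodes)))
  linkNet(cbind(lab[e[, 1L]], lab[e[, 2L]]), nodeLabels = lab)
}

.checkGenArgs <- function(numNodes, probs) {
  if (numNodes < 4L) stop("generators require numNodes >= 4")
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
}

#' The Zachary karate-club network
#'
#' The canonical 34-node, 78-edge social network of a university karate
#' club, packaged as a plain-text edge list. A standard small benchmark
#' for link prediction: mean degree 4.588, maximum degree 17, diameter
#' 5, transitivity about 0.256, degree assortativity about -0.476.
#'
#' @return a [LinkNet-class]
#' @examples
#' networkStats(karateClub())
#' @export
karateClub <- function() {
  readEdgeList(system.file("extdata", "karate.edgelist",
                           package = "sqwalk", mustWork = TRUE))
}
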