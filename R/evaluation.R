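#' Randomly split edges into training and probe sets
#'
#' Draws a uniform partition of the edge set without replacement:
#' |E_T| = round(eta * M) edges become the training set, the rest the
#' probe set of held-out "missing" links. Deterministic for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param net a [LinkNet-class] with at least 2 edges
#' @param eta training fraction in (0, 1)
#' @param seed optional integer seed
#' @return an [EdgeSplit-class]
#' @examples
#' sp <- splitEdges(karateClub(), eta = 0.8, seed = 1)
#' nrow(trainEdges(sp))  # 62
#' @export
splitEdges <- function(net, eta, seed = NULL) {
  if (!is.numeric(eta) || length(eta) != 1L || eta <= 0 || eta >= 1)
    stop("eta must be a single value in (0, 1)")
  e <- edgeMatrix(net)
  m <- nrow(e)
  if (m < 2L) stop("need at least 2 edges to split")
  mT <- as.integer(round(eta * m))
  mT <- max(1L, min(m - 1L, mT))   # keep both sets non-trivial at the margins
  idx <- .withSeed(seed, sample.int(m, mT))
  new("EdgeSplit", eta = eta,
      trainEdges = e[sort(idx), , drop = FALSE],
      probeEdges = e[sort(setdiff(seq_len(m), idx)), , drop = FALSE],
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @rdname trainEdges
#' @aliases trainEdges,EdgeSplit-method
#' @export
setMethod("trainEdges", "EdgeSplit", function(x) x@trainEdges)

#' @rdname probeEdges
#' @aliases probeEdges,EdgeSplit-method
#' @export
setMethod("probeEdges", "EdgeSplit", function(x) x@probeEdges)

setMethod("show", "EdgeSplit", function(object) {
  cat("EdgeSplit: eta =", object@eta, "->",
      nrow(object@trainEdges), "training /",
      nrow(object@probeEdges), "probe edges",
      if (!is.na(object@seed)) paste0("(seed ", object@seed, ")") else "", "\n")
})

#' Training graph of a split
#'
#' Builds the graph G~ = (V, E_T) the scorers see: same node set as the
#' full network (isolated nodes are kept), edges restricted to E_T.
#'
#' @param net the full [LinkNet-class]
#' @param split an [EdgeSplit-class] of `net`
#' @return a [LinkNet-class]
#' @export
trainingNet <- function(net, split) {
  lab <- nodeLabels(net)
  e <- trainEdges(split)
  linkNet(cbind(lab[e[, 1L]], lab[e[, 2L]]), nodeLabels = lab)
}

# scores of the probe edges and of the nonexistent pairs (E_U minus E)
.aucPools <- function(scores, net, split) {
  S <- scoreMatrix(scores)
  n <- numNodes(net)
  if (nrow(S) != n) stop("score matrix does not match network size")
  pe <- probeEdges(split)
  if (nrow(pe) == 0L) stop("probe set is empty")
  nonIdx <- which(upper.tri(S) & adjacency(net) == 0)
  if (length(nonIdx) == 0L) stop("no nonexistent pairs to compare against")
  list(probe = S[pe], non = S[nonIdx])
}

.aucResult <- function(n1, n2, n, sampled) {
  auc <- (n1 + 0.5 * n2) / n
  se <- if (sampled) {
    ex2 <- (n1 + 0.25 * n2) / n           # E[x^2] for x in {0, 0.5, 1}
    sqrt(max(ex2 - auc^2, 0) / n)
  } else 0
  new("AUCResult", n = n, n1 = n1, n2 = n2, auc = auc, stdError = se)
}

#' Sampled AUC of a score matrix against a split
#'
#' Estimates the probability that a randomly chosen probe link outscores
#' a randomly chosen nonexistent link (a pair absent from the full edge
#' set E, the training edges excluded as candidates' negatives as well).
#' Draws `nSamples` independent (probe, nonexistent) pairs with
#' replacement; strict wins count 1, ties (within `tieTol`) count 0.5:
#' AUC = (n1 + 0.5 n2) / n. The default sample count keeps the absolute
#' sampling error of the estimate below 1e-3.
#'
#' @param scores a [LinkScores-class] computed on the training graph
#' @param net the full [LinkNet-class] (defines the nonexistent pool)
#' @param split the [EdgeSplit-class] used
#' @param nSamples number of sampled comparisons (default 672400)
#' @param seed optional integer seed
#' @param tieTol absolute tolerance for calling two scores tied
#' @return an [AUCResult-class]
#' @export
aucSampled <- function(scores, net, split, nSamples = 672400L, seed = NULL,
                       tieTol = 1e-12) {
  pools <- .aucPools(scores, net, split)
  nSamples <- as.integer(nSamples)
  if (nSamples < 1L) stop("nSamples must be positive")
  dif <- .withSeed(seed, {
    pools$probe[sample.int(length(pools$probe), nSamples, replace = TRUE)] -
      pools$non[sample.int(length(pools$non), nSamples, replace = TRUE)]
  })
  n2 <- sum(abs(dif) <= tieTol)
  n1 <- sum(dif > tieTol)
  .aucResult(n1, n2, nSamples, sampled = TRUE)
}

#' Exhaustive AUC over all probe-by-nonexistent comparisons
#'
#' Enumerates every (probe, nonexistent) pair instead of sampling; the
#' reference the sampler is validated against. Guarded to products of at
#' most 1e7 comparisons.
#'
#' @inheritParams aucSampled
#' @return an [AUCResult-class] with `stdError = 0`
#' @export
aucExhaustive <- function(scores, net, split, tieTol = 1e-12) {
  pools <- .aucPools(scores, net, split)
  nTot <- length(pools$probe) * length(pools$non)
  if (nTot > 1e7)
    stop("exhaustive AUC guard exceeded: ", format(nTot), " comparisons")
  dif <- outer(pools$probe, pools$non, `-`)
  n2 <- sum(abs(dif) <= tieTol)
  n1 <- sum(dif > tieTol)
  .aucResult(n1, n2, nTot, sampled = FALSE)
}

setMethod("show", "AUCResult", function(object) {
  cat(sprintf("AUC = %.4f  (n = %g, wins = %g, ties = %g, se = %.2g)\n",
              object@auc, object@n, object@n1, object@n2, object@stdError))
})

#' Precision among the top-L ranked candidates
#'
#' Ranks every pair in E_U minus E_T (all unordered non-training pairs —
#' probe links are candidates, training edges are not) by descending
#' score, breaking ties lexicographically by label pair for
#' reproducibility, and reports the fraction of the top L that are true
#' probe links. Default L = floor(|E_T| / 3).
#'
#' @inheritParams aucSampled
#' @param L number of top candidates to evaluate; default
#'   `floor(nrow(trainEdges(split)) / 3)`
#' @return a [PrecisionResult-class]
#' @export
precisionAt <- function(scores, net, split, L = NULL) {
  S <- scoreMatrix(scores)
  n <- numNodes(net)
  if (nrow(S) != n) stop("score matrix does not match network size")
  te <- trainEdges(split)
  pe <- probeEdges(split)
  if (is.null(L)) L <- nrow(te) %/% 3L
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  inTrain <- matrix(FALSE, n, n)
  inTrain[te] <- TRUE
  cand <- which(upper.tri(S) & !inTrain, arr.ind = TRUE)
  if (L > nrow(cand))
    stop("L = ", L, " exceeds the ", nrow(cand), " candidate pairs")
  lab <- nodeLabels(net)
  o <- order(-S[cand], lab[cand[, 1L]], lab[cand[, 2L]])
  top <- cand[o[seq_len(L)], , drop = FALSE]
  inProbe <- matrix(FALSE, n, n)
  inProbe[pe] <- TRUE
  l <- as.integer(sum(inProbe[top]))
  new("PrecisionResult", L = L, l = l, precision = l / L)
}

setMethod("show", "PrecisionResult", function(object) {
  cat(sprintf("Precision@%d = %.4f  (%d probe links recovered)\n",
              object@L, object@precision, object@l))
})

#' Benchmark several methods over repeated random splits
#'
#' The full evaluation protocol: for each repetition, split the edges at
#' fraction `eta`, score every method on the training graph, and
#' evaluate sampled AUC and precision@L. Per-repetition seeds are
#' derived from `seed` so the whole run is reproducible from
#' (network, configuration, seed).
#'
#' @param net the full [LinkNet-class]
#' @param methods character vector of method names (see
#'   [linkPredMethods()]); validated before any computation
#' @param eta training fraction (default 0.9)
#' @param repetitions number of independent splits (default 10)
#' @param nSamples AUC sample count per evaluation (default 672400)
#' @param seed integer seed for the whole benchmark (default 1)
#' @param L precision cut-off; default floor(|E_T| / 3) per split
#' @param steps walk length for the `"sqwalk"` method (default 2)
#' @return list with elements `report` (per-method mean/sd data.frame),
#'   `runs` (per-repetition data.frame) and `config`
#' @examples
#' net <- samplePlantedPartition(seed = 7)
#' b <- benchmarkLinkPrediction(net, c("sqwalk", "CN"), repetitions = 2,
#'                              nSamples = 10000, seed = 1)
#' b$report
#' @export
benchmarkLinkPrediction <- function(net, methods, eta = 0.9,
                                    repetitions = 10L, nSamples = 672400L,
                                    seed = 1L, L = NULL, steps = 2L) {
  bad <- setdiff(methods, linkPredMethods())
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  runs <- list()
  for (r in seq_len(repetitions)) {
    splitSeed <- (as.integer(seed) + 7919L * r) %% .Machine$integer.max
    sp <- splitEdges(net, eta, seed = splitSeed)
    tn <- trainingNet(net, sp)
    for (meth in methods) {
      sc <- if (meth == "sqwalk") quantumWalkScores(tn, steps = steps)
            else similarityScores(tn, meth)
      auc <- aucSampled(sc, net, sp, nSamples = nSamples,
                        seed = splitSeed + 1L)
      pre <- precisionAt(sc, net, sp, L = L)
      runs[[length(runs) + 1L]] <- data.frame(
        method = meth, repetition = r, auc = auc@auc,
        precision = pre@precision, L = pre@L)
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs$method), function(d) {
    data.frame(method = d$method[1L],
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
               precision_mean = mean(d$precision),
               precision_sd = stats::sd(d$precision))
  }))
  agg <- agg[match(unique(methods), agg$method), , drop = FALSE]
  rownames(agg) <- NULL
  rownames(runs) <- NULL
  list(report = agg, runs = runs,
       config = list(eta = eta, repetitions = repetitions,
                     nSamples = nSamples, seed = as.integer(seed),
                     steps = steps, numNodes = numNodes(net),
                     numEdges = numEdges(net)))
}

#' Write a benchmark report as JSON and TSV
#'
#' Serialises the output of [benchmarkLinkPrediction()]: a JSON document
#' carrying the resolved configuration plus per-method summaries, and a
#' flat TSV twin of the summary table.
#'
#' @param bench list returned by [benchmarkLinkPrediction()]
#' @param jsonPath,tsvPath output paths (either may be NULL to skip)
#' @return invisibly, the report data.frame
#' @export
writeBenchmark <- function(bench, jsonPath = NULL, tsvPath = NULL) {
  if (!is.null(jsonPath)) {
    doc <- c(bench$config, list(results = bench$report))
    jsonlite::write_json(doc, jsonPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  if (!is.null(tsvPath))
    utils::write.table(bench$report, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(bench$report)
}
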