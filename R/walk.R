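#' Coin operator of the simplified quantum walk
#'
#' Grover-style diffusion coin built from the training graph: entry
#' (j, k) is -A_jk + 2 |Gamma(j, k)| where Gamma(j, k) is the set of
#' common neighbours (so the diagonal equals 2 d_j). No normalising
#' denominator is applied: the model deliberately abandons unitarity so
#' that observed amplitudes track raw similarity rather than a
#' probability distribution.
#'
#' @param net a [LinkNet-class] (the training graph)
#' @return symmetric N x N numeric matrix
#' @examples
#' tri <- linkNet(rbind(c("a","b"), c("b","c"), c("a","c")))
#' buildCoin(tri)  # 4 on the diagonal, 1 off it
#' @export
buildCoin <- function(net) {
  A <- adjacency(net)
  -A + 2 * (A %*% A)
}

#' Shift operator of the simplified quantum walk
#'
#' Block-diagonal 2N x 2N matrix over the coin (x) position space with
#' state layout `c(psi0, psi1)`. The |0> block is the identity — a
#' self-loop on every node, which damps traceback (amplitude oscillating
#' between a node pair). The |1> block is the degree-normalised
#' adjacency D^-1 A: each node hops to its neighbourhood treated as a
#' whole. Rows of dangling (degree-0) nodes in the |1> block are zero.
#'
#' @param net a [LinkNet-class]
#' @return 2N x 2N numeric matrix `[I, 0; 0, D^-1 A]`
#' @export
buildShift <- function(net) {
  A <- adjacency(net)
  n <- nrow(A)
  d <- rowSums(A)
  P <- A / ifelse(d > 0, d, 1)  # zero rows stay zero for dangling nodes
  S <- matrix(0, 2 * n, 2 * n)
  S[seq_len(n), seq_len(n)] <- diag(n)
  S[n + seq_len(n), n + seq_len(n)] <- P
  S
}

#' Evolution operator from coin and shift
#'
#' U = S . blockdiag(G, G): the coin acts identically in both coin
#' sectors, then the shift moves amplitude. In block form this is
#' `[G, 0; 0, (D^-1 A) G]`.
#'
#' @param coin N x N coin matrix from [buildCoin()]
#' @param shift 2N x 2N shift matrix from [buildShift()]
#' @return 2N x 2N numeric matrix
#' @export
buildEvolution <- function(coin, shift) {
  n <- nrow(coin)
  if (nrow(shift) != 2L * n || ncol(shift) != 2L * n)
    stop("dimension mismatch: shift must be 2N x 2N for an N x N coin")
  C2 <- matrix(0, 2L * n, 2L * n)
  C2[seq_len(n), seq_len(n)] <- coin
  C2[n + seq_len(n), n + seq_len(n)] <- coin
  shift %*% C2
}

#' Initial walk state: equal superposition
#'
#' All 2N amplitudes set to the same constant alpha. The default
#' convention is alpha = 1/sqrt(N) (equal superposition); alpha = 1/N is
#' available by flag. All downstream rankings — hence AUC and precision —
#' are invariant to this choice, since every score scales linearly in
#' alpha.
#'
#' @param net a [LinkNet-class]
#' @param amplitude `"inv_sqrt_n"` (default) or `"inv_n"`
#' @return a [WalkState-class] at step 0
#' @export
initialState <- function(net, amplitude = c("inv_sqrt_n", "inv_n")) {
  amplitude <- match.arg(amplitude)
  n <- numNodes(net)
  if (n < 1L) stop("network must have at least one node")
  alpha <- if (amplitude == "inv_sqrt_n") 1 / sqrt(n) else 1 / n
  new("WalkState", amplitudes = rep(alpha, 2L * n), step = 0L,
      initAmplitude = alpha)
}

#' Evolve the walk state
#'
#' Applies the evolution operator `steps` times: psi(t + steps) =
#' U^steps psi(t). Because U is block-diagonal, the two coin sectors
#' evolve independently: psi0 by G^t, psi1 by ((D^-1 A) G)^t.
#'
#' @param evolution 2N x 2N matrix from [buildEvolution()]
#' @param state a [WalkState-class]
#' @param steps non-negative integer
#' @return the evolved [WalkState-class]
#' @export
evolveWalk <- function(evolution, state, steps) {
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 0L) stop("steps must be a non-negative integer")
  if (length(state@amplitudes) != nrow(evolution))
    stop("state length does not match evolution operator dimension")
  psi <- state@amplitudes
  for (i in seq_len(steps)) psi <- as.vector(evolution %*% psi)
  new("WalkState", amplitudes = psi, step = state@step + steps,
      initAmplitude = state@initAmplitude)
}

setMethod("show", "WalkState", function(object) {
  n <- length(object@amplitudes) / 2L
  cat("WalkState over", n, "nodes at step", object@step, "\n")
  cat("  initial amplitude:", format(object@initAmplitude, digits = 6), "\n")
})

# Per-node observation totals psi0(t)[j] + psi1(t)[j] after a t-step
# walk from the uniform initial state.
.walkNodeTotals <- function(net, steps, amplitude) {
  n <- numNodes(net)
  A <- adjacency(net)
  G <- buildCoin(net)
  d <- rowSums(A)
  P <- A / ifelse(d > 0, d, 1)
  st <- initialState(net, amplitude)
  psi0 <- st@amplitudes[seq_len(n)]
  psi1 <- st@amplitudes[n + seq_len(n)]
  PG <- P %*% G
  for (i in seq_len(steps)) {
    psi0 <- as.vector(G %*% psi0)
    psi1 <- as.vector(PG %*% psi1)
  }
  psi0 + psi1
}

#' Score one candidate link with the walk model
#'
#' The observation functional: after a `steps`-step walk from the
#' uniform initial state, the ordered score of pair (j, k) is
#' `(|Gamma(j,k)| / trainingEdgeCount) * (psi0(t)[j] + psi1(t)[j])`.
#' It is zero whenever j and k share no common neighbour, and it reads
#' the amplitude at j only, so the ordered score is asymmetric; see
#' [quantumWalkScores()] for the symmetrised matrix.
#'
#' @param net the training-graph [LinkNet-class]
#' @param j,k distinct node indices or labels
#' @param trainingEdgeCount |E_T|, the number of edges in the training
#'   graph (defaults to `numEdges(net)`)
#' @param steps walk length t (default 2)
#' @param amplitude initial amplitude convention, see [initialState()]
#' @return numeric score
#' @export
scoreLink <- function(net, j, k, trainingEdgeCount = numEdges(net),
                      steps = 2L, amplitude = c("inv_sqrt_n", "inv_n")) {
  amplitude <- match.arg(amplitude)
  j <- .resolveNode(net, j); k <- .resolveNode(net, k)
  if (j == k) stop("scoreLink requires two distinct nodes")
  if (trainingEdgeCount < 1L) stop("trainingEdgeCount must be >= 1")
  cn <- commonNeighbors(net, j, k)
  if (cn == 0L) return(0)
  tot <- .walkNodeTotals(net, as.integer(steps), amplitude)
  (cn / trainingEdgeCount) * tot[j]
}

#' Score every candidate pair with the walk model
#'
#' Computes the full similarity matrix of the simplified quantum walk on
#' the training graph. The ordered score for (j, k) reads the amplitude
#' at j; the stored unordered score symmetrises the two orientations by
#' their mean (default) or sum. `symmetrization = "none"` returns the
#' raw ordered (asymmetric) matrix instead of a [LinkScores-class]
#' object.
#'
#' @param net the training-graph [LinkNet-class]
#' @param trainingEdgeCount |E_T| (defaults to `numEdges(net)`)
#' @param steps walk length t; the model's operating point is 2, long
#'   enough to pick up common-neighbour structure, short enough to
#'   avoid traceback build-up
#' @param symmetrization `"mean"` (default), `"sum"`, or `"none"`
#' @param amplitude initial amplitude convention, see [initialState()]
#' @return a [LinkScores-class]; a plain matrix for `"none"`
#' @examples
#' net <- karateClub()
#' sc <- quantumWalkScores(net)
#' scoreMatrix(sc)[1, 3]
#' @export
quantumWalkScores <- function(net, trainingEdgeCount = numEdges(net),
                              steps = 2L,
                              symmetrization = c("mean", "sum", "none"),
                              amplitude = c("inv_sqrt_n", "inv_n")) {
  symmetrization <- match.arg(symmetrization)
  amplitude <- match.arg(amplitude)
  if (trainingEdgeCount < 1L) stop("trainingEdgeCount must be >= 1")
  steps <- as.integer(steps)
  tot <- .walkNodeTotals(net, steps, amplitude)
  pref <- .cnMatrix(net) / trainingEdgeCount
  ordered <- pref * tot          # row j scaled by amplitude total at j
  diag(ordered) <- 0
  S <- switch(symmetrization,
    mean = (ordered + t(ordered)) / 2,
    sum  = ordered + t(ordered),
    none = return(ordered))
  new("LinkScores", scores = S, method = "sqwalk",
      params = list(steps = steps, trainingEdgeCount = trainingEdgeCount,
                    symmetrization = symmetrization, amplitude = amplitude))
}

#' @rdname scoreMatrix
#' @aliases scoreMatrix,LinkScores-method
#' @export
setMethod("scoreMatrix", "LinkScores", function(x) x@scores)

setMethod("show", "LinkScores", function(object) {
  cat("LinkScores (", object@method, ") over ", nrow(object@scores),
      " nodes\n", sep = "")
  if (length(object@params))
    cat("  params:", paste(names(object@params),
        vapply(object@params, function(p) paste(format(p), collapse = ","), ""),
        sep = "=", collapse = ", "), "\n")
})

#' Write ranked candidate scores as TSV
#'
#' Emits columns `node_label_1`, `node_label_2`, `score` for every
#' unordered candidate pair, sorted by descending score with a
#' deterministic lexicographic tie-break on the label pair. Pairs that
#' are edges of `net` (the training graph) are excluded, matching the
#' ranking used by precision evaluation.
#'
#' @param scores a [LinkScores-class]
#' @param net the [LinkNet-class] the scores were computed on
#' @param path output TSV path
#' @param includeTraining if TRUE, rank every unordered pair including
#'   training edges
#' @return invisibly, the ranked data.frame that was written
#' @export
writeScores <- function(scores, net, path, includeTraining = FALSE) {
  S <- scoreMatrix(scores)
  n <- numNodes(net)
  if (nrow(S) != n) stop("score matrix does not match network size")
  ut <- upper.tri(S)
  if (!includeTraining) ut <- ut & adjacency(net) == 0
  idx <- which(ut, arr.ind = TRUE)
  lab <- nodeLabels(net)
  df <- data.frame(node_label_1 = lab[idx[, 1L]],
                   node_label_2 = lab[idx[, 2L]],
                   score = S[idx], stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$node_label_1, df$node_label_2), , drop = FALSE]
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
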