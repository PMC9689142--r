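#' @import methods
NULL

#' LinkNet: an undirected simple network
#'
#' Container for an undirected simple graph: a symmetric 0/1 adjacency
#' matrix with zero diagonal, plus the original node labels in the order
#' they were first seen. All scoring and evaluation functions in the
#' package operate on this class.
#'
#' @slot nodeLabels character vector of original node labels; position
#'   `j` is the internal index of that node.
#' @slot adjacency symmetric numeric 0/1 matrix with zero diagonal.
#'
#' @seealso [linkNet()], [readEdgeList()], [networkStats()]
#' @export
setClass("LinkNet",
  slots = c(nodeLabels = "character", adjacency = "matrix")
)

setValidity("LinkNet", function(object) {
  A <- object@adjacency
  n <- length(object@nodeLabels)
  msgs <- character()
  if (nrow(A) != ncol(A)) msgs <- c(msgs, "adjacency must be square")
  if (nrow(A) != n) msgs <- c(msgs, "adjacency dimension must match nodeLabels")
  if (anyDuplicated(object@nodeLabels)) msgs <- c(msgs, "node labels must be unique")
  if (length(msgs) == 0L) {
    if (!all(A %in% c(0, 1))) msgs <- c(msgs, "adjacency entries must be 0 or 1")
    if (!isSymmetric(unname(A))) msgs <- c(msgs, "adjacency must be symmetric")
    if (n > 0L && any(diag(A) != 0)) msgs <- c(msgs, "self-loops are not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' EdgeSplit: random partition of edges into training and probe sets
#'
#' Holds the outcome of randomly dividing the observed edge set E into a
#' training set E_T (fraction eta, used to build the graph that scorers
#' see) and a probe set E_P (the held-out "missing" links to recover).
#'
#' @slot eta numeric in (0,1); |E_T| = round(eta * |E|).
#' @slot trainEdges integer matrix, two columns, one training edge per
#'   row with node indices ordered (first < second).
#' @slot probeEdges integer matrix, same layout, the held-out edges.
#' @slot seed integer seed the split was drawn with (NA if none given).
#'
#' @seealso [splitEdges()], [trainingNet()]
#' @export
setClass("EdgeSplit",
  slots = c(eta = "numeric", trainEdges = "matrix",
            probeEdges = "matrix", seed = "integer")
)

setValidity("EdgeSplit", function(object) {
  msgs <- character()
  if (ncol(object@trainEdges) != 2L || ncol(object@probeEdges) != 2L)
    msgs <- c(msgs, "edge matrices must have two columns")
  if (length(object@eta) != 1L || object@eta <= 0 || object@eta >= 1)
    msgs <- c(msgs, "eta must be a single value in (0,1)")
  if (length(msgs)) msgs else TRUE
})

#' LinkScores: symmetric matrix of candidate-link scores
#'
#' A symmetric N x N matrix of real similarity scores over unordered node
#' pairs, zero on the diagonal, as produced by [similarityScores()] or
#' [quantumWalkScores()]. Larger scores mean "more likely a missing link"
#' for every method in the package.
#'
#' @slot scores symmetric numeric matrix with zero diagonal.
#' @slot method character name of the scoring method.
#' @slot params list of method parameters used (walk steps, dampings, ...).
#'
#' @export
setClass("LinkScores",
  slots = c(scores = "matrix", method = "character", params = "list")
)

setValidity("LinkScores", function(object) {
  S <- object@scores
  msgs <- character()
  if (nrow(S) != ncol(S)) msgs <- c(msgs, "score matrix must be square")
  else {
    if (!isSymmetric(unname(S), tol = 1e-8))
      msgs <- c(msgs, "score matrix must be symmetric")
    if (nrow(S) > 0L && any(abs(diag(S)) > 1e-12))
      msgs <- c(msgs, "score matrix diagonal must be zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' WalkState: amplitude vector of the walk
#'
#' The 2N-dimensional real state of the simplified quantum walk, stored
#' as two N-blocks: coin state |0> (self-loop direction) first, coin
#' state |1> (towards the neighbourhood as a whole) second.
#'
#' @slot amplitudes numeric vector of length 2N, layout `c(psi0, psi1)`.
#' @slot step integer number of evolution steps applied so far.
#' @slot initAmplitude the uniform starting amplitude alpha.
#'
#' @seealso [initialState()], [evolveWalk()]
#' @export
setClass("WalkState",
  slots = c(amplitudes = "numeric", step = "integer", initAmplitude = "numeric")
)

setValidity("WalkState", function(object) {
  msgs <- character()
  if (length(object@amplitudes) %% 2L != 0L)
    msgs <- c(msgs, "amplitude vector length must be even (2N)")
  if (object@step < 0L) msgs <- c(msgs, "step must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' AUCResult: tally of sampled or exhaustive AUC comparisons
#'
#' @slot n total number of probe-vs-nonexistent comparisons.
#' @slot n1 comparisons where the probe link scored strictly higher.
#' @slot n2 comparisons that tied (within tolerance).
#' @slot auc (n1 + 0.5 n2) / n.
#' @slot stdError Monte-Carlo standard error of the AUC estimate
#'   (0 for exhaustive enumeration).
#'
#' @seealso [aucSampled()], [aucExhaustive()]
#' @export
setClass("AUCResult",
  slots = c(n = "numeric", n1 = "numeric", n2 = "numeric",
            auc = "numeric", stdError = "numeric")
)

setValidity("AUCResult", function(object) {
  msgs <- character()
  if (object@n1 + object@n2 > object@n + 1e-9)
    msgs <- c(msgs, "n1 + n2 cannot exceed n")
  if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
    msgs <- c(msgs, "auc must lie in [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' PrecisionResult: precision among the top-L ranked candidates
#'
#' @slot L number of top-ranked non-training candidate pairs evaluated.
#' @slot l how many of those are probe (held-out) links.
#' @slot precision l / L.
#'
#' @seealso [precisionAt()]
#' @export
setClass("PrecisionResult",
  slots = c(L = "integer", l = "integer", precision = "numeric")
)

setValidity("PrecisionResult", function(object) {
  msgs <- character()
  if (object@l < 0L || object@l > object@L)
    msgs <- c(msgs, "l must lie in [0, L]")
  if (length(msgs)) msgs else TRUE
})
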