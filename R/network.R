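#' Construct a LinkNet from an edge list
#'
#' Builds an undirected simple network from a two-column edge list.
#' Labels are mapped to internal indices in order of first appearance,
#' duplicate edges (in either orientation) are collapsed, and self-loop
#' rows are dropped with a warning — the model assumes a simple graph
#' and adds self-loops itself through the shift operator.
#'
#' @param edges two-column matrix or data.frame; character labels or
#'   positive integer indices, one edge per row. May have zero rows.
#' @param nodeLabels optional character vector of labels fixing the node
#'   set (useful to keep isolated nodes, e.g. after an edge split).
#' @return a [LinkNet-class] object
#' @examples
#' net <- linkNet(rbind(c("a", "b"), c("b", "c")))
#' numNodes(net)  # 3
#' numEdges(net)  # 2
#' @export
linkNet <- function(edges, nodeLabels = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) < 2L)
    stop("`edges` must have two columns")
  ends <- if (length(edges)) cbind(as.character(edges[, 1L]),
                                   as.character(edges[, 2L]))
          else matrix(character(), ncol = 2L)
  if (is.null(nodeLabels)) {
    nodeLabels <- unique(as.vector(t(ends)))  # first-appearance order
  } else {
    nodeLabels <- as.character(nodeLabels)
    missing <- setdiff(unique(as.vector(ends)), nodeLabels)
    if (length(missing))
      stop("edge endpoints not in `nodeLabels`: ", paste(missing, collapse = ", "))
  }
  n <- length(nodeLabels)
  A <- matrix(0, n, n)
  if (nrow(ends)) {
    i <- match(ends[, 1L], nodeLabels)
    j <- match(ends[, 2L], nodeLabels)
    loops <- i == j
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      i <- i[!loops]; j <- j[!loops]
    }
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  new("LinkNet", nodeLabels = nodeLabels, adjacency = A)
}

#' @rdname numNodes
#' @aliases numNodes,LinkNet-method
#' @export
setMethod("numNodes", "LinkNet", function(x) length(x@nodeLabels))

#' @rdname numEdges
#' @aliases numEdges,LinkNet-method
#' @export
setMethod("numEdges", "LinkNet", function(x) as.integer(sum(x@adjacency) / 2))

#' @rdname nodeLabels
#' @aliases nodeLabels,LinkNet-method
#' @export
setMethod("nodeLabels", "LinkNet", function(x) x@nodeLabels)

#' @rdname adjacency
#' @aliases adjacency,LinkNet-method
#' @export
setMethod("adjacency", "LinkNet", function(x) x@adjacency)

#' @rdname degrees
#' @aliases degrees,LinkNet-method
#' @export
setMethod("degrees", "LinkNet", function(x) {
  d <- as.integer(rowSums(x@adjacency))
  names(d) <- x@nodeLabels
  d
})

#' @rdname edgeMatrix
#' @aliases edgeMatrix,LinkNet-method
#' @export
setMethod("edgeMatrix", "LinkNet", function(x) {
  idx <- which(upper.tri(x@adjacency) & x@adjacency == 1, arr.ind = TRUE)
  e <- unname(idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE])
  storage.mode(e) <- "integer"
  e
})

setMethod("show", "LinkNet", function(object) {
  cat("LinkNet with", numNodes(object), "nodes and", numEdges(object),
      "edges\n")
  lab <- object@nodeLabels
  if (length(lab) > 6L) lab <- c(lab[1:6], "...")
  cat("  labels:", paste(lab, collapse = " "), "\n")
})

#' Neighbour set of a node
#'
#' @param net a [LinkNet-class]
#' @param j node index (1-based) or label
#' @return integer vector of neighbour indices of j
#' @export
neighborSet <- function(net, j) {
  j <- .resolveNode(net, j)
  which(net@adjacency[j, ] == 1)
}

.resolveNode <- function(net, j) {
  if (is.character(j)) {
    idx <- match(j, net@nodeLabels)
    if (is.na(idx)) stop("unknown node label: ", j)
    return(idx)
  }
  j <- as.integer(j)
  if (is.na(j) || j < 1L || j > numNodes(net))
    stop("node index out of range: ", j)
  j
}

#' Number of common neighbours of a node pair
#'
#' Counts |N(j) /\ N(k)|, the core similarity signal shared by the walk's
#' coin operator and the local baseline indices. Symmetric in (j, k);
#' for j == k the set-intersection semantics give the degree d_j.
#'
#' @param net a [LinkNet-class]
#' @param j,k node indices (1-based) or labels
#' @return integer count
#' @export
commonNeighbors <- function(net, j, k) {
  j <- .resolveNode(net, j); k <- .resolveNode(net, k)
  sum(net@adjacency[j, ] * net@adjacency[k, ])
}

# N x N common-neighbour count matrix; entry (j,k) = |N(j) /\ N(k)|,
# diagonal = degrees (A^2 gives both at once).
.cnMatrix <- function(net) {
  A <- net@adjacency
  A %*% A
}

.asIgraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net@adjacency, mode = "undirected")
}

#' Summary statistics of a network
#'
#' Computes the descriptive statistics customarily tabulated for complex
#' networks: node and edge counts, mean degree 2M/N, maximum degree,
#' diameter (longest shortest path; on the largest connected component
#' when the graph is disconnected), global clustering coefficient
#' (transitivity: 3 x triangles over connected triples) and degree
#' assortativity (Pearson correlation of degrees across edges).
#'
#' @param net a [LinkNet-class] with at least 2 nodes
#' @return one-row data.frame with columns numNodes, numEdges,
#'   meanDegree, maxDegree, diameter, clustering, assortativity
#' @examples
#' networkStats(karateClub())
#' @export
networkStats <- function(net) {
  n <- numNodes(net)
  if (n < 2L) stop("networkStats needs at least 2 nodes")
  m <- numEdges(net)
  g <- .asIgraph(net)
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    big <- which.max(comps$csize)
    gd <- igraph::induced_subgraph(g, which(comps$membership == big))
  } else gd <- g
  diam <- if (igraph::vcount(gd) > 1L)
    as.numeric(igraph::diameter(gd, unconnected = FALSE)) else 0
  cc <- igraph::transitivity(g, type = "global")
  if (is.nan(cc)) cc <- 0
  rho <- if (m > 0L) suppressWarnings(igraph::assortativity_degree(g)) else NaN
  if (is.na(rho) || is.nan(rho)) {
    warning("degenerate assortativity (regular or empty graph); reporting 0")
    rho <- 0
  }
  data.frame(numNodes = n, numEdges = m, meanDegree = 2 * m / n,
             maxDegree = if (n) max(degrees(net)) else 0L,
             diameter = diam, clustering = cc, assortativity = rho)
}

#' Read a network from a plain-text edge list
#'
#' One edge per line: two whitespace- or comma-separated node labels;
#' lines starting with `#` and blank lines are ignored. Extra tokens
#' after the first two are ignored. Duplicate edges are collapsed and
#' self-loop lines dropped with a warning.
#'
#' @param path file path
#' @param delimiter optional separator regex; default splits on commas
#'   and/or whitespace
#' @return a [LinkNet-class]
#' @seealso [writeEdgeList()]
#' @export
readEdgeList <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  sep <- if (is.null(delimiter)) "[,[:space:]]+" else delimiter
  toks <- strsplit(trimws(lines), sep)
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad))
    stop("parse error at line ", lineNo[bad[1L]],
         ": expected two node labels, got '", lines[bad[1L]], "'")
  ends <- t(vapply(toks, function(tk) tk[1:2], character(2L)))
  linkNet(ends)
}

#' Write a network as a plain-text edge list
#'
#' Emits the same dialect [readEdgeList()] accepts: one edge per line,
#' two labels separated by `delimiter`, lexicographically ordered edges.
#'
#' @param net a [LinkNet-class]
#' @param path output file path
#' @param delimiter separator string (default single space)
#' @return invisibly, the path
#' @export
writeEdgeList <- function(net, path, delimiter = " ") {
  e <- edgeMatrix(net)
  lab <- nodeLabels(net)
  writeLines(paste(lab[e[, 1L]], lab[e[, 2L]], sep = delimiter), path)
  invisible(path)
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG. NULL seed leaves the RNG alone.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
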