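#' Number of nodes
#' @param x a [LinkNet-class] object
#' @return integer node count N
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges
#' @param x a [LinkNet-class] object
#' @return integer edge count M
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Node labels
#' @param x a [LinkNet-class] object
#' @return character vector of original labels, in internal index order
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' Adjacency matrix
#' @param x a [LinkNet-class] object
#' @return symmetric numeric 0/1 matrix
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Node degrees
#' @param x a [LinkNet-class] object
#' @return integer vector d_j = |N(j)|
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' Edge matrix
#' @param x a [LinkNet-class] object
#' @return two-column integer matrix of edges, node indices ordered
#'   within each row, rows sorted lexicographically
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' Score matrix of a LinkScores object
#' @param x a [LinkScores-class] object
#' @return symmetric numeric matrix of pairwise scores
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' Training edges of a split
#' @param x an [EdgeSplit-class] object
#' @return two-column integer matrix E_T
#' @export
setGeneric("trainEdges", function(x) standardGeneric("trainEdges"))

#' Probe (held-out) edges of a split
#' @param x an [EdgeSplit-class] object
#' @return two-column integer matrix E_P
#' @export
setGeneric("probeEdges", function(x) standardGeneric("probeEdges"))
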