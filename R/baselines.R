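#' Names of all registered link-prediction methods
#'
#' The walk model plus the fourteen classical comparison indices:
#' nine local common-neighbour-family indices (CN, Salton, Jaccard,
#' Sorenson, HPI, HDI, PA, AA, RA), two path-based indices (LP, Katz),
#' two Laplacian/random-walk indices (ACT, CosPlus) and the
#' neighbour-contribution walk index (NC).
#'
#' @return character vector of method names accepted by
#'   [similarityScores()]
#' @export
linkPredMethods <- function() {
  c("sqwalk", .localNames, "LP", "Katz", "ACT", "CosPlus", "NC")
}

.localNames <- c("CN", "Salton", "Jaccard", "Sorenson", "HPI", "HDI",
                 "PA", "AA", "RA")

.asLinkScores <- function(S, method, params = list()) {
  S <- (S + t(S)) / 2           # kill symmetric round-off
  diag(S) <- 0
  new("LinkScores", scores = unname(S), method = method, params = params)
}

# divide elementwise, mapping x/0 to 0
.safeDiv <- function(num, den) ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)

#' Local (common-neighbour family) similarity indices
#'
#' Nine neighbourhood-based indices, each a symmetric score matrix with
#' zero diagonal. With CN = |N(j) /\ N(k)| and degrees d:
#' CN itself; Salton = CN / sqrt(d_j d_k); Jaccard = CN / |N(j) \/ N(k)|;
#' Sorenson = 2 CN / (d_j + d_k); HPI = CN / min(d_j, d_k);
#' HDI = CN / max(d_j, d_k); PA = d_j d_k;
#' AA = sum over common neighbours z of 1 / ln d_z;
#' RA = sum over common neighbours z of 1 / d_z.
#' Ratio indices return 0 where the denominator is 0. AA weights for
#' d_z <= 1 are guarded to 0 (such nodes can never be common
#' neighbours, so the guard is unreachable on valid graphs).
#'
#' @param net a [LinkNet-class] (training graph)
#' @param name one of CN, Salton, Jaccard, Sorenson, HPI, HDI, PA, AA, RA
#' @return a [LinkScores-class]
#' @export
localIndex <- function(net, name) {
  if (!name %in% .localNames)
    stop("unknown local index: ", name)
  A <- adjacency(net)
  d <- rowSums(A)
  CN <- A %*% A
  S <- switch(name,
    CN = CN,
    Salton = .safeDiv(CN, sqrt(outer(d, d))),
    Jaccard = .safeDiv(CN, outer(d, d, `+`) - CN),
    Sorenson = .safeDiv(2 * CN, outer(d, d, `+`)),
    HPI = .safeDiv(CN, outer(d, d, pmin)),
    HDI = .safeDiv(CN, outer(d, d, pmax)),
    PA = outer(d, d),
    AA = {
      w <- ifelse(d > 1, 1 / log(pmax(d, 2)), 0)
      A %*% (w * A)             # sum_z A_jz w_z A_zk
    },
    RA = {
      w <- ifelse(d > 0, 1 / pmax(d, 1), 0)
      A %*% (w * A)
    })
  .asLinkScores(S, name)
}

#' Path-based similarity indices: Local Path and Katz
#'
#' LP = A^2 + alpha A^3 counts paths of length two plus damped paths of
#' length three. Katz = (I - alpha A)^-1 - I sums all path lengths with
#' geometric damping; its series converges only for
#' alpha < 1 / lambda_max(A), which is enforced.
#'
#' @param net a [LinkNet-class]
#' @param name `"LP"` or `"Katz"`
#' @param lpAlpha damping for LP (default 0.001)
#' @param katzAlpha damping for Katz; default `min(0.01, 0.85 / lambda_max)`
#' @return a [LinkScores-class]
#' @export
pathIndex <- function(net, name, lpAlpha = 0.001, katzAlpha = NULL) {
  if (!name %in% c("LP", "Katz")) stop("unknown path index: ", name)
  A <- adjacency(net)
  n <- nrow(A)
  if (name == "LP") {
    A2 <- A %*% A
    S <- A2 + lpAlpha * (A2 %*% A)
    return(.asLinkScores(S, "LP", list(lpAlpha = lpAlpha)))
  }
  lamMax <- if (n > 0 && any(A > 0))
    max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values)) else 0
  if (is.null(katzAlpha))
    katzAlpha <- if (lamMax > 0) min(0.01, 0.85 / lamMax) else 0.01
  if (lamMax > 0 && katzAlpha * lamMax >= 1)
    stop("Katz series diverges: alpha * lambda_max = ",
         format(katzAlpha * lamMax), " >= 1")
  S <- solve(diag(n) - katzAlpha * A) - diag(n)
  .asLinkScores(S, "Katz", list(katzAlpha = katzAlpha))
}

#' Laplacian-pseudoinverse similarity indices: ACT and Cos+
#'
#' With L+ the Moore-Penrose pseudoinverse of the graph Laplacian D - A:
#' the average-commute-time index scores a pair by the reciprocal of its
#' commute distance, ACT(j,k) = 1 / (l+_jj + l+_kk - 2 l+_jk), so that —
#' like every other index here — larger means more similar; Cos+ is the
#' cosine similarity l+_jk / sqrt(l+_jj l+_kk). Pairs lying in different
#' connected components are scored 0 (their commute time is infinite).
#'
#' @param net a [LinkNet-class] with at least one edge
#' @param name `"ACT"` or `"CosPlus"`
#' @return a [LinkScores-class]
#' @export
laplacianIndex <- function(net, name) {
  if (!name %in% c("ACT", "CosPlus")) stop("unknown Laplacian index: ", name)
  A <- adjacency(net)
  if (sum(A) == 0) stop("Laplacian indices need at least one edge")
  d <- rowSums(A)
  Lp <- MASS::ginv(diag(d) - A)
  dg <- diag(Lp)
  comp <- igraph::components(.asIgraph(net))$membership
  same <- outer(comp, comp, `==`)
  if (name == "ACT") {
    den <- outer(dg, dg, `+`) - 2 * Lp     # commute distance (resistance)
    S <- ifelse(same & den > 1e-12, 1 / ifelse(den > 1e-12, den, 1), 0)
  } else {
    S <- ifelse(same, .safeDiv(Lp, sqrt(pmax(outer(dg, dg), 0))), 0)
  }
  .asLinkScores(S, name)
}

#' Neighbour-contribution walk index (NC)
#'
#' A three-step local random-walk index. With P = D^-1 A the transition
#' matrix, pi_jk(l) = (P^l)_jk, and per-node weight
#' w_j = sum over z in N(j) of d_z / (d_max * 2M), the score is
#' s(j,k) = sum over l in {2,3} of w_j pi_jk(l) + w_k pi_kj(l).
#' The walk horizon is fixed at 3.
#'
#' @param net a [LinkNet-class] with at least one edge
#' @return a [LinkScores-class]
#' @export
ncIndex <- function(net) {
  A <- adjacency(net)
  if (sum(A) == 0) stop("NC needs at least one edge")
  d <- rowSums(A)
  m <- sum(A) / 2
  P <- A / ifelse(d > 0, d, 1)
  w <- as.vector(A %*% d) / (max(d) * 2 * m)
  P2 <- P %*% P
  Pi <- P2 + P2 %*% P                      # pi(2) + pi(3)
  S <- w * Pi + t(w * Pi)                  # w_j pi_jk + w_k pi_kj
  .asLinkScores(S, "NC", list(ncSteps = 3L))
}

#' Score candidate links with any registered method
#'
#' Single dispatcher over the walk model (`"sqwalk"`) and the fourteen
#' baseline indices; see [linkPredMethods()] for the names. Extra
#' arguments are forwarded to the method.
#'
#' @param net the training-graph [LinkNet-class]
#' @param method method name
#' @param ... forwarded: `steps`, `symmetrization`, `amplitude`,
#'   `trainingEdgeCount` for `"sqwalk"`; `lpAlpha`, `katzAlpha` for the
#'   path indices
#' @return a [LinkScores-class]
#' @examples
#' net <- karateClub()
#' cn <- similarityScores(net, "CN")
#' qw <- similarityScores(net, "sqwalk")
#' @export
similarityScores <- function(net, method, ...) {
  if (!is.character(method) || length(method) != 1L ||
      !method %in% linkPredMethods())
    stop("unknown method '", method, "'; see linkPredMethods()")
  if (method == "sqwalk") return(quantumWalkScores(net, ...))
  if (method %in% .localNames) return(localIndex(net, method))
  if (method %in% c("LP", "Katz")) return(pathIndex(net, method, ...))
  if (method %in% c("ACT", "CosPlus")) return(laplacianIndex(net, method))
  ncIndex(net)
}
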