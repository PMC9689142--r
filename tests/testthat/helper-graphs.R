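# Small graphs and independent oracles used across the suite.

# path 0 - 1 - ... - (n-1), labels "0".."n-1"
pathNet <- function(n = 3L) {
  lab <- as.character(seq_len(n) - 1L)
  linkNet(cbind(lab[-n], lab[-1L]), nodeLabels = lab)
}

triangleNet <- function() {
  linkNet(rbind(c("0", "1"), c("1", "2"), c("0", "2")))
}

completeNet <- function(n) {
  lab <- as.character(seq_len(n) - 1L)
  e <- t(utils::combn(lab, 2L))
  linkNet(e, nodeLabels = lab)
}

edgelessNet <- function(n) {
  linkNet(matrix(character(), ncol = 2L),
          nodeLabels = as.character(seq_len(n) - 1L))
}

# Literal operator construction: shift assembled from outer products of
# basis vectors |c, j> (index c*N + j), coin entry by entry from
# neighbourhood-set intersections, evolution as S . (I_2 (x) G).
# Independent of the package's block-assembly path.
kronEvolutionOracle <- function(net) {
  A <- adjacency(net)
  n <- nrow(A)
  basis <- function(cc, j) { v <- numeric(2L * n); v[cc * n + j] <- 1; v }
  S <- matrix(0, 2L * n, 2L * n)
  for (j in seq_len(n)) {
    S <- S + basis(0L, j) %*% t(basis(0L, j))
    nb <- which(A[j, ] == 1)
    for (k in nb)
      S <- S + (1 / length(nb)) * basis(1L, j) %*% t(basis(1L, k))
  }
  G <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    cn <- length(intersect(which(A[j, ] == 1), which(A[k, ] == 1)))
    G[j, k] <- -A[j, k] + 2 * cn
  }
  list(evolution = S %*% kronecker(diag(2), G), shift = S, coin = G)
}

# Brute-force set-arithmetic evaluation of one local index on one pair.
bruteLocalIndex <- function(net, name, j, k) {
  A <- adjacency(net)
  Nj <- which(A[j, ] == 1)
  Nk <- which(A[k, ] == 1)
  com <- intersect(Nj, Nk)
  cn <- length(com)
  dj <- length(Nj); dk <- length(Nk)
  switch(name,
    CN = cn,
    Salton = if (dj * dk == 0) 0 else cn / sqrt(dj * dk),
    Jaccard = { u <- length(union(Nj, Nk)); if (u == 0) 0 else cn / u },
    Sorenson = if (dj + dk == 0) 0 else 2 * cn / (dj + dk),
    HPI = if (min(dj, dk) == 0) 0 else cn / min(dj, dk),
    HDI = if (max(dj, dk) == 0) 0 else cn / max(dj, dk),
    PA = dj * dk,
    AA = if (cn == 0) 0 else
      sum(vapply(com, function(z) {
        dz <- sum(A[z, ]); if (dz > 1) 1 / log(dz) else 0
      }, numeric(1))),
    RA = if (cn == 0) 0 else
      sum(vapply(com, function(z) 1 / sum(A[z, ]), numeric(1))),
    stop("oracle does not know index ", name))
}

# Random simple graph for property loops (always >= 1 edge unless p = 0).
randomNet <- function(n, p, seed) sampleErdosRenyi(n, p, seed = seed)

# Scores object wrapping an arbitrary symmetric matrix, for crafting
# perfect / constant / random scorers in evaluation tests.
rawScores <- function(S, method = "crafted") {
  S <- (S + t(S)) / 2
  diag(S) <- 0
  new("LinkScores", scores = S, method = method, params = list())
}
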