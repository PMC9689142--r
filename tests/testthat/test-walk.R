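test_that("coin operator mixes adjacency and common-neighbour counts", {
  expect_equal(buildCoin(triangleNet()),
               matrix(c(4, 1, 1, 1, 4, 1, 1, 1, 4), 3))
  expect_equal(buildCoin(pathNet(3)),
               matrix(c(2, -1, 2, -1, 4, -1, 2, -1, 2), 3))
  expect_equal(buildCoin(edgelessNet(4)), matrix(0, 4, 4))
  # symmetry and diagonal = 2 d_j on random graphs
  for (seed in 1:5) {
    net <- randomNet(9, 0.4, seed = seed)
    G <- buildCoin(net)
    expect_true(isSymmetric(G))
    expect_equal(diag(G), 2 * as.numeric(degrees(net)), ignore_attr = TRUE)
  }
})

test_that("shift operator is identity over degree-normalised adjacency", {
  S <- buildShift(pathNet(3))
  expect_equal(S[1:3, 1:3], diag(3))
  expect_equal(S[4:6, 4:6],
               matrix(c(0, 0.5, 0, 1, 0, 1, 0, 0.5, 0), 3))
  expect_equal(S[1:3, 4:6], matrix(0, 3, 3))
  # non-dangling rows of the hop block sum to 1; dangling rows are zero
  net <- linkNet(rbind(c("a", "b")), nodeLabels = c("a", "b", "c"))
  Sb <- buildShift(net)[4:6, 4:6]
  expect_equal(rowSums(Sb), c(1, 1, 0))
  expect_equal(buildShift(edgelessNet(1))[2, 2], 0)
})

test_that("evolution operator has the block closed form", {
  net <- pathNet(3)
  G <- buildCoin(net)
  U <- buildEvolution(G, buildShift(net))
  expect_equal(U[1:3, 1:3], G)
  expect_equal(U[4:6, 4:6],
               matrix(c(-1, 2, -1, 4, -1, 4, -1, 2, -1), 3))
  expect_equal(U[1:3, 4:6], matrix(0, 3, 3))
  expect_equal(buildEvolution(buildCoin(edgelessNet(3)),
                              buildShift(edgelessNet(3))),
               matrix(0, 6, 6))
  expect_error(buildEvolution(G, diag(4)), "dimension")
})

test_that("block evolution equals the literal operator construction", {
  for (seed in 1:12) {
    n <- 4 + seed %% 5
    net <- randomNet(n, 0.45, seed = 100 + seed)
    oracle <- kronEvolutionOracle(net)
    U <- buildEvolution(buildCoin(net), buildShift(net))
    expect_equal(U, oracle$evolution, tolerance = 1e-13)
    expect_equal(buildShift(net), oracle$shift, tolerance = 1e-13)
    expect_equal(buildCoin(net), oracle$coin, tolerance = 1e-13)
  }
})

test_that("initial state is the requested uniform superposition", {
  net4 <- edgelessNet(4)
  expect_equal(initialState(net4)@amplitudes, rep(0.5, 8))
  expect_equal(initialState(net4, "inv_n")@amplitudes, rep(0.25, 8))
  expect_equal(initialState(edgelessNet(1))@amplitudes, c(1, 1))
  expect_identical(initialState(net4)@step, 0L)
})

test_that("evolution reproduces the hand-computed two-step amplitudes", {
  net <- pathNet(3)
  U <- buildEvolution(buildCoin(net), buildShift(net))
  st0 <- initialState(net)

  expect_equal(evolveWalk(U, st0, 0)@amplitudes, st0@amplitudes)
  expect_error(evolveWalk(U, st0, -1), "non-negative")

  st2 <- evolveWalk(U, st0, 2)
  expect_identical(st2@step, 2L)
  expect_equal(st2@amplitudes[1:3], c(10, 2, 10) / sqrt(3))
  expect_equal(st2@amplitudes[4:6], c(8, 5, 8) / sqrt(3))
})

test_that("repeated single steps equal one multi-step application", {
  for (seed in 1:6) {
    net <- randomNet(8, 0.4, seed = 200 + seed)
    U <- buildEvolution(buildCoin(net), buildShift(net))
    st0 <- initialState(net)
    onebyone <- st0
    for (i in 1:4) onebyone <- evolveWalk(U, onebyone, 1)
    atonce <- evolveWalk(U, st0, 4)
    expect_equal(onebyone@amplitudes, atonce@amplitudes, tolerance = 1e-10)
    expect_identical(onebyone@step, atonce@step)
  }
})

test_that("single-link scores follow the observation functional", {
  net <- pathNet(3)
  expect_equal(scoreLink(net, "0", "2", trainingEdgeCount = 2), 9 / sqrt(3))
  expect_equal(scoreLink(net, "0", "1", trainingEdgeCount = 2), 0)  # no CN
  expect_error(scoreLink(net, 1, 1), "distinct")
  # steps = 0: prefactor times the two uniform initial amplitudes
  expect_equal(scoreLink(net, "0", "2", trainingEdgeCount = 2, steps = 0),
               (1 / 2) * 2 / sqrt(3))
})

test_that("score matrices are symmetric, CN-masked and convention-covariant", {
  net <- pathNet(3)
  scSum <- quantumWalkScores(net, trainingEdgeCount = 2, symmetrization = "sum")
  S <- scoreMatrix(scSum)
  expect_equal(S[1, 3], 18 / sqrt(3))
  expect_equal(S[1, 2], 0)
  expect_equal(S[2, 3], 0)

  scMean <- quantumWalkScores(net, trainingEdgeCount = 2)
  expect_equal(2 * scoreMatrix(scMean), S)

  for (seed in 1:5) {
    g <- randomNet(10, 0.35, seed = 300 + seed)
    m <- scoreMatrix(quantumWalkScores(g, trainingEdgeCount = max(1, numEdges(g))))
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 0))
    cn <- adjacency(g) %*% adjacency(g)
    off <- upper.tri(m)
    expect_true(all(m[off][cn[off] == 0] == 0))
    # amplitude convention 1/N scales every score by 1/sqrt(N)
    mN <- scoreMatrix(quantumWalkScores(g, trainingEdgeCount = max(1, numEdges(g)),
                                        amplitude = "inv_n"))
    expect_equal(mN, m / sqrt(numNodes(g)))
  }
  # ordered scores come back raw under symmetrization = "none"
  ord <- quantumWalkScores(net, trainingEdgeCount = 2, symmetrization = "none")
  expect_true(is.matrix(ord))
  expect_equal(ord + t(ord), S)
})

test_that("score TSV output ranks candidates with deterministic ties", {
  net <- karateClub()
  sc <- quantumWalkScores(net)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- writeScores(sc, net, f)
  expect_identical(nrow(df), 483L)  # 34*33/2 - 78 candidate pairs
  expect_identical(names(df), c("node_label_1", "node_label_2", "score"))
  expect_true(all(diff(df$score) <= 1e-12))
  back <- utils::read.delim(f)
  expect_equal(back$score, df$score)
})
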