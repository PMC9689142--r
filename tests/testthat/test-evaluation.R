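test_that("edge splits have the right sizes and are seed-deterministic", {
  net <- randomNet(10, 0.5, seed = 1)      # M should be around 22
  m <- numEdges(net)
  sp <- splitEdges(net, 0.9, seed = 7)
  expect_identical(nrow(trainEdges(sp)), as.integer(round(0.9 * m)))
  expect_identical(nrow(trainEdges(sp)) + nrow(probeEdges(sp)), m)
  # disjoint and exhaustive partition
  key <- function(e) paste(e[, 1], e[, 2])
  expect_length(intersect(key(trainEdges(sp)), key(probeEdges(sp))), 0)
  expect_setequal(c(key(trainEdges(sp)), key(probeEdges(sp))),
                  key(edgeMatrix(net)))

  sp2 <- splitEdges(net, 0.9, seed = 7)
  expect_identical(trainEdges(sp2), trainEdges(sp))
  expect_error(splitEdges(net, 1.5), "eta")
  expect_error(splitEdges(net, 0), "eta")

  k <- karateClub()
  spk <- splitEdges(k, 0.8, seed = 1)
  expect_identical(nrow(trainEdges(spk)), 62L)
  expect_identical(nrow(probeEdges(spk)), 16L)
  tn <- trainingNet(k, spk)
  expect_identical(numNodes(tn), 34L)      # isolated nodes kept
  expect_identical(numEdges(tn), 62L)
})

test_that("exhaustive AUC implements the tally arithmetic", {
  net <- pathNet(6)                         # 5 edges, 10 candidate pairs
  sp <- splitEdges(net, 0.8, seed = 3)      # 4 train / 1 probe
  n <- numNodes(net)
  pe <- probeEdges(sp)

  up <- matrix(0, n, n); up[pe] <- 10; up <- up + t(up)
  expect_equal(aucExhaustive(rawScores(up), net, sp)@auc, 1.0)

  down <- matrix(5, n, n); down[pe] <- 0; down[pe[, 2:1, drop = FALSE]] <- 0
  expect_equal(aucExhaustive(rawScores(down), net, sp)@auc, 0.0)

  flat <- rawScores(matrix(1, n, n))
  resFlat <- aucExhaustive(flat, net, sp)
  expect_identical(resFlat@auc, 0.5)        # all ties, exactly
  expect_identical(resFlat@n2, resFlat@n)
})

test_that("sampled AUC agrees with its exhaustive reference", {
  net <- samplePlantedPartition(60, 3, 0.5, 0.05, seed = 21)
  sp <- splitEdges(net, 0.8, seed = 4)
  sc <- quantumWalkScores(trainingNet(net, sp))
  ref <- aucExhaustive(sc, net, sp)@auc
  devs <- vapply(1:20, function(s) {
    r <- aucSampled(sc, net, sp, nSamples = 50000, seed = 600 + s)
    abs(r@auc - ref) / r@stdError
  }, numeric(1))
  expect_true(mean(devs <= 4) >= 0.95)
  # perfect / constant behaviour also holds under sampling
  n <- numNodes(net)
  up <- matrix(0, n, n); up[probeEdges(sp)] <- 1; up <- up + t(up)
  expect_equal(aucSampled(rawScores(up), net, sp, 10000, seed = 1)@auc, 1.0)
  expect_identical(aucSampled(rawScores(matrix(2, n, n)), net, sp,
                              10000, seed = 1)@auc, 0.5)
})

test_that("AUC and precision are invariant under monotone score transforms", {
  net <- randomNet(30, 0.25, seed = 8)
  sp <- splitEdges(net, 0.8, seed = 9)
  sc <- similarityScores(trainingNet(net, sp), "RA")
  S <- scoreMatrix(sc)
  warped <- rawScores(exp(3 * S) - 1)       # strictly increasing, fixes 0
  expect_identical(aucSampled(sc, net, sp, 20000, seed = 11)@auc,
                   aucSampled(warped, net, sp, 20000, seed = 11)@auc)
  expect_identical(precisionAt(sc, net, sp, L = 10)@precision,
                   precisionAt(warped, net, sp, L = 10)@precision)
})

test_that("precision counts probe links among the top-L candidates", {
  net <- pathNet(8)
  sp <- splitEdges(net, 0.7, seed = 5)      # 5 train / 2 probe
  n <- numNodes(net)
  pe <- probeEdges(sp)
  up <- matrix(0, n, n); up[pe] <- 10; up <- up + t(up)
  perfect <- rawScores(up)
  res <- precisionAt(perfect, net, sp, L = nrow(pe))
  expect_equal(res@precision, 1.0)
  expect_identical(res@l, nrow(pe))
  # scores that miss every probe link
  res0 <- precisionAt(rawScores(matrix(0, n, n) - up), net, sp, L = 2)
  expect_equal(res0@precision, 0.0)
  # default L is floor(|E_T| / 3)
  expect_identical(precisionAt(perfect, net, sp)@L, nrow(trainEdges(sp)) %/% 3L)
  expect_error(precisionAt(perfect, net, sp, L = 10000), "exceeds")
  # once L grows past |E_P| a perfect scorer's precision must fall
  p2 <- precisionAt(perfect, net, sp, L = nrow(pe) + 3L)
  expect_lt(p2@precision, 1.0)
  expect_identical(p2@l, nrow(pe))
})

test_that("benchmark runs are reproducible and method-order independent", {
  net <- samplePlantedPartition(40, 2, 0.5, 0.05, seed = 31)
  b1 <- benchmarkLinkPrediction(net, c("CN", "RA", "sqwalk"), eta = 0.8,
                                repetitions = 2, nSamples = 5000, seed = 17)
  expect_identical(nrow(b1$report), 3L)
  expect_true(all(b1$runs$auc >= 0 & b1$runs$auc <= 1))
  b2 <- benchmarkLinkPrediction(net, c("CN", "RA", "sqwalk"), eta = 0.8,
                                repetitions = 2, nSamples = 5000, seed = 17)
  expect_identical(b1$report, b2$report)
  b3 <- benchmarkLinkPrediction(net, c("sqwalk", "RA", "CN"), eta = 0.8,
                                repetitions = 2, nSamples = 5000, seed = 17)
  expect_equal(b1$report[order(b1$report$method), ],
               b3$report[order(b3$report$method), ], ignore_attr = TRUE)
  expect_error(benchmarkLinkPrediction(net, c("CN", "bogus")), "unknown")

  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeBenchmark(b1, f1, f2)
  doc <- jsonlite::read_json(f1)
  expect_identical(doc$eta, 0.8)
  expect_length(doc$results, 3L)
  expect_identical(nrow(utils::read.delim(f2)), 3L)
})

test_that("sampler dispersion at the default sample count stays below 1e-3", {
  # the default n = 672,400 is chosen so the Monte-Carlo standard deviation
  # of the AUC estimate is bounded by 0.5/sqrt(n) ~ 6.1e-4 < 1e-3
  net <- samplePlantedPartition(seed = 101)
  sp <- splitEdges(net, 0.9, seed = 102)
  sc <- quantumWalkScores(trainingNet(net, sp))
  aucs <- vapply(1:50, function(s) {
    aucSampled(sc, net, sp, nSamples = 672400L, seed = 7000 + s)@auc
  }, numeric(1))
  expect_lt(stats::sd(aucs), 1e-3)
  expect_lt(max(aucSampled(sc, net, sp, nSamples = 672400L,
                           seed = 7100)@stdError), 1e-3)
})
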