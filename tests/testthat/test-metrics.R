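graphFromMatrix <- function(w, tau = 1e-6) thresholdGraph(connectivityMatrix(w), tau)

test_that("weighted clustering reproduces hand-computed closed forms", {
  wTri <- matrix(0, 3, 3)
  wTri[1, 2] <- wTri[2, 1] <- 1
  wTri[1, 3] <- wTri[3, 1] <- 1
  wTri[2, 3] <- wTri[3, 2] <- 1
  cl <- clusteringOnnela(graphFromMatrix(wTri))
  expect_equal(unname(cl$perNode), c(1, 1, 1))
  expect_equal(cl$mean, 1)

  wPath <- matrix(0, 3, 3)
  wPath[1, 2] <- wPath[2, 1] <- 1
  wPath[2, 3] <- wPath[3, 2] <- 1
  expect_equal(unname(clusteringOnnela(graphFromMatrix(wPath))$perNode),
               c(0, 0, 0))

  wTri[2, 3] <- wTri[3, 2] <- 0.125
  cl2 <- clusteringOnnela(graphFromMatrix(wTri))
  expect_equal(unname(cl2$perNode[1]), 0.5)   # (1*1*0.125)^(1/3)

  expect_error(clusteringOnnela(igraph::make_empty_graph(0)), "empty")
})

test_that("path lengths and nodal efficiency match their closed forms", {
  w1 <- matrix(0, 3, 3); w1[1, 2] <- w1[2, 1] <- 0.5
  d <- shortestPathLengths(graphFromMatrix(w1))
  expect_equal(d[1, 2], 2)                     # 1/w
  expect_equal(d[1, 3], Inf)

  wPath <- matrix(0, 3, 3)
  wPath[1, 2] <- wPath[2, 1] <- 1
  wPath[2, 3] <- wPath[3, 2] <- 1
  g <- graphFromMatrix(wPath)
  expect_equal(shortestPathLengths(g)[1, 3], 2)
  expect_equal(characteristicPathLength(g)$lp, 4 / 3)

  # complete unit-weight graph: lp = 1
  wK <- matrix(1, 4, 4); diag(wK) <- 0
  expect_equal(characteristicPathLength(graphFromMatrix(wK))$lp, 1)

  # adding an isolated node leaves lp unchanged but reports exclusions
  wIso <- rbind(cbind(wPath, 0), 0)
  plIso <- characteristicPathLength(graphFromMatrix(wIso))
  expect_equal(plIso$lp, 4 / 3)
  expect_gt(plIso$excludedPairs, 0)

  # unit-weight star, N = 4: center 1, leaves 2/3, isolated node 0
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  en <- nodalEfficiency(graphFromMatrix(star))
  expect_equal(unname(en), c(1, 2 / 3, 2 / 3, 2 / 3))
  wI <- rbind(cbind(star, 0), 0)
  expect_equal(unname(nodalEfficiency(graphFromMatrix(wI))[5]), 0)
})

test_that("modularity matches hand values and Louvain attains the optimum", {
  # one clique under a single community: Q = 0
  wK <- matrix(1, 5, 5); diag(wK) <- 0
  g <- graphFromMatrix(wK)
  expect_equal(modularityQ(g, rep(1, 5)), 0)

  # two disconnected unit triangles: optimal Q = 0.5, Louvain finds it
  w2 <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    w2[e[1], e[2]] <- w2[e[2], e[1]] <- 1
  g2 <- graphFromMatrix(w2)
  expect_equal(modularityQ(g2, c(1, 1, 1, 2, 2, 2)), 0.5)
  lou <- modularityLouvain(g2, seed = 3, restarts = 5)
  expect_equal(lou$q, 0.5)

  expect_error(
    modularityLouvain(suppressWarnings(graphFromMatrix(matrix(0, 3, 3)))),
    "edgeless")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(57)
  for (i in 1:40) {
    n <- sample(5:12, 1)
    w <- randomConnMatrix(n, density = runif(1, 0.3, 0.9))
    if (sum(w) == 0) next
    g <- graphFromMatrix(w)
    expect_equal(unname(shortestPathLengths(g)), fwOracle(w),
                 tolerance = 1e-10)
    expect_equal(unname(clusteringOnnela(g)$perNode), onnelaOracle(w),
                 tolerance = 1e-10)
    memb <- sample(1:3, n, replace = TRUE)
    expect_equal(modularityQ(g, memb), qOracle(w, memb), tolerance = 1e-10)
    lou <- modularityLouvain(g, seed = i, restarts = 5)
    expect_equal(lou$q, qOracle(w, lou$membership), tolerance = 1e-10)
    # Louvain's Q beats the all-singletons and a random partition
    expect_gte(lou$q, qOracle(w, seq_len(n)) - 1e-12)
    expect_gte(lou$q, qOracle(w, memb) - 1e-12)
  }
})

test_that("nodal efficiency is relabeling-invariant and monotone in weight scaling", {
  set.seed(58)
  for (i in 1:10) {
    w <- randomConnMatrix(8, density = 0.5, wMin = 0.05, wMax = 0.45)
    if (sum(w) == 0) next
    en <- nodalEfficiency(graphFromMatrix(w))
    perm <- sample(8)
    enP <- nodalEfficiency(graphFromMatrix(w[perm, perm]))
    expect_equal(unname(enP), unname(en)[perm], tolerance = 1e-12)
    enScaled <- nodalEfficiency(graphFromMatrix(pmin(2 * w, 1)))
    expect_true(all(enScaled >= en - 1e-12))
  }
})

test_that("hubness scoring follows the four-criterion convention", {
  star <- matrix(0, 10, 10); star[1, 2:10] <- star[2:10, 1] <- 1
  h <- hubnessScore(graphFromMatrix(star))
  expect_equal(unname(h[1]), 4)               # center: all four criteria
  expect_true(all(h[-1] <= 1))                # leaves: at most one

  ring <- ringLattice(12, k = 2, rewireFrac = 0)
  hr <- hubnessScore(graphFromMatrix(ring))
  expect_length(unique(hr), 1)                 # full symmetry -> one score

  expect_error(hubnessScore(graphFromMatrix(matrix(1, 4, 4) - diag(4))),
               "5 nodes")
})

test_that("small-worldness flags the lattice regime and passes ER calibration", {
  set.seed(59)
  lat <- ringLattice(60, k = 4, rewireFrac = 0.05)
  swLat <- smallWorldness(graphFromMatrix(lat), nNull = 20, seed = 2)
  expect_gt(swLat$sigma, 1)
  expect_true(swLat$sigmaClusterOk)

  er <- erMatrix(60, meanDegree = 8)
  swEr <- smallWorldness(graphFromMatrix(er), nNull = 20, seed = 2)
  expect_lt(abs(swEr$sigma - 1), 0.2)

  expect_error(smallWorldness(graphFromMatrix(lat), nNull = 0), "nNull")
  disc <- matrix(0, 20, 20)
  disc[1, 2] <- disc[2, 1] <- 1
  expect_error(suppressWarnings(smallWorldness(graphFromMatrix(disc),
                                               nNull = 20)),
               "component")
})

test_that("computeAllMetrics is deterministic and composes the parts", {
  w2 <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    w2[e[1], e[2]] <- w2[e[2], e[1]] <- 1
  # connect the triangles weakly so the largest component spans the graph
  w2[3, 4] <- w2[4, 3] <- 0.05
  g <- graphFromMatrix(w2)
  m1 <- computeAllMetrics(g, seed = 4, nNull = 20, restarts = 5)
  m2 <- computeAllMetrics(g, seed = 4, nNull = 20, restarts = 5)
  expect_identical(m1, m2)
  expect_equal(m1$global$cp, clusteringOnnela(g)$mean)
  expect_equal(m1$global$lp, characteristicPathLength(g)$lp)
  expect_equal(m1$nodal$enod, unname(nodalEfficiency(g)))
  expect_error(computeAllMetrics(igraph::make_empty_graph(0)), "empty")
})
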