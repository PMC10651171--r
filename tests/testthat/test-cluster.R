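mkMaps <- function(values) lapply(values, function(v) matrix(v, 1, 1))

test_that("rank-sum Z maps match closed form and are antisymmetric", {
  a <- mkMaps(c(1, 2, 3)); b <- mkMaps(c(4, 5, 6))
  zm <- zmapUnpaired(a, b)
  expect_equal(zm$z[1, 1], -1.9640, tolerance = 1e-4)
  expect_equal(zmapUnpaired(b, a)$z[1, 1], -zm$z[1, 1])
  same <- zmapUnpaired(mkMaps(c(1, 2, 3)), mkMaps(c(1, 2, 3)))
  expect_equal(same$z[1, 1], 0)
  # agreement with stats::wilcox.test (normal approx, no continuity)
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(5, 0.5)
    zm <- zmapUnpaired(mkMaps(x), mkMaps(y))
    wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(zm$p[1, 1], wt$p.value, tolerance = 1e-10)
    expect_equal(zm$z[1, 1], oracleRankSumZ(x, y), tolerance = 1e-12)
  }
  # midrank tie handling agrees with the oracle
  x <- c(1, 1, 2, 3); y <- c(2, 2, 3, 4)
  expect_equal(zmapUnpaired(mkMaps(x), mkMaps(y))$z[1, 1], oracleRankSumZ(x, y),
               tolerance = 1e-12)
})

craftedZmap <- function(z) list(z = z, p = 2 * pnorm(-abs(z)))

test_that("candidate clusters respect the minimum size and wrapping rules", {
  lay <- gridLayout(4, 4)
  g <- buildNeighborGraph(lay, 4)
  nCh <- 16; nT <- 30
  # empty mask
  expect_length(findCandidateClusters(craftedZmap(matrix(0, nCh, nT)), g), 0)
  # a 3-channel patch persisting 20 samples is dropped (min 4 channels)
  z <- matrix(0, nCh, nT); z[1:3, 5:24] <- 3
  expect_length(findCandidateClusters(craftedZmap(z), g), 0)
  # two 5-channel same-sign patches at adjacent samples sharing one channel merge
  z2 <- matrix(0, nCh, nT)
  z2[c(1, 2, 3, 4, 5), 10] <- 3        # rows 1:4 + col-neighbour 5
  z2[c(5, 6, 7, 8, 9), 11] <- 3
  cl <- findCandidateClusters(craftedZmap(z2), g)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$size, 10)
  expect_equal(cl[[1]]$nChannels, 9)
  # sharing zero channels: two clusters
  z3 <- matrix(0, nCh, nT)
  z3[1:4, 10] <- 3
  z3[c(13, 14, 15, 16), 11] <- 3
  expect_length(findCandidateClusters(craftedZmap(z3), g), 2)
  # opposite signs never merge
  z4 <- matrix(0, nCh, nT)
  z4[1:5, 10] <- 3; z4[1:5, 11] <- -3
  expect_length(findCandidateClusters(craftedZmap(z4), g), 2)
  # wrapping is transitive across consecutive samples
  z5 <- matrix(0, nCh, nT)
  for (t in 10:14) z5[1:4, t] <- 3
  cl5 <- findCandidateClusters(craftedZmap(z5), g)
  expect_length(cl5, 1)
  expect_equal(cl5[[1]]$latencyMs, c(9, 13) * 1000 / 250)
})

test_that("exhaustive Monte Carlo p equals the brute-force oracle exactly", {
  # 4 vs 4 subjects, 6 mutually neighbouring channels x 5 samples
  lay <- gridLayout(3, 2, 1.5)          # all pairwise distances <= 4 cm
  g <- buildNeighborGraph(lay, 4)
  expect_true(all(lengths(adjacency(g)) == 5))
  set.seed(11)
  mapsA <- lapply(1:4, function(i) matrix(rnorm(30, mean = 2.5), 6, 5))
  mapsB <- lapply(1:4, function(i) matrix(rnorm(30), 6, 5))
  res <- permutationTest(mapsA, mapsB, g, nPartitions = 10000, seed = 1)
  expect_true(res@exhaustive)
  expect_equal(res@nPartitions, 70)
  oracle <- oraclePermutationStats(mapsA, mapsB)
  expect_equal(sort(permDistribution(res)), sort(oracle), tolerance = 1e-12)
  expect_gt(length(clusters(res)), 0)
  # oracle recomputes each cluster's statistic from its own Z values; a tiny
  # slack absorbs last-bit arithmetic differences at exact ties
  X <- t(vapply(c(mapsA, mapsB), as.numeric, numeric(30)))
  for (cl in clusters(res)) {
    pts <- (cl$members[, "time"] - 1) * 6 + cl$members[, "channel"]
    oracleStat <- max(vapply(pts, function(j)
      abs(oracleRankSumZ(X[1:4, j], X[5:8, j])), 0))
    expect_equal(cl$mcP, mean(oracle >= oracleStat - 1e-9))
  }
})

test_that("permutation inference is monotone and invariant to subject order", {
  lay <- gridLayout(3, 2, 1.5)
  g <- buildNeighborGraph(lay, 4)
  set.seed(12)
  mapsA <- lapply(1:5, function(i) matrix(rnorm(30, 2), 6, 5))
  mapsB <- lapply(1:5, function(i) matrix(rnorm(30), 6, 5))
  r1 <- permutationTest(mapsA, mapsB, g, nPartitions = 252, seed = 3)
  shifted <- lapply(mapsA, function(m) m + 1)
  r2 <- permutationTest(shifted, mapsB, g, nPartitions = 252, seed = 3)
  pos1 <- Filter(function(cl) cl$sign == "+", clusters(r1))
  pos2 <- Filter(function(cl) cl$sign == "+", clusters(r2))
  expect_gte(pos2[[1]]$stat, pos1[[1]]$stat)
  expect_lte(pos2[[1]]$mcP, pos1[[1]]$mcP)
  # permuting subject order within a group changes nothing
  r3 <- permutationTest(mapsA[c(3, 1, 5, 2, 4)], mapsB, g, nPartitions = 252, seed = 3)
  expect_equal(zMatrix(r3), zMatrix(r1))
  expect_identical(clusters(r3)[[1]]$mcP, clusters(r1)[[1]]$mcP)
})

test_that("combined clustered effects are point averages over cluster members", {
  cluster <- list(members = cbind(channel = c(1, 1, 2, 2), time = c(1, 2, 1, 2)),
                  sign = "+", nChannels = 2, size = 4, stat = 3, latencyMs = c(0, 4),
                  mcP = 0.01)
  maps <- list(matrix(7, 3, 3), matrix(c(2, 2, 0, 2, 2, 0, 0, 0, 0), 3, 3))
  ce <- combinedClusterEffect(maps, cluster)
  expect_equal(ce[1], 7)          # constant map -> the constant
  expect_equal(ce[2], 2)          # +2 on the cluster points
  half <- matrix(0, 3, 3); half[1, 1:2] <- 2
  expect_equal(combinedClusterEffect(list(half), cluster), 1)   # half the points
  expect_equal(combinedClusterEffect(list(-maps[[2]]), cluster), -2)  # linearity
})

test_that("null permutation inference is calibrated at the dataset level", {
  lay <- gridLayout(4, 4)
  g <- buildNeighborGraph(lay, 4)
  hits <- vapply(1:60, function(i) {
    mp <- simulateEffectMaps(10, 10, lay, 30, seed = 4000 + i)
    r <- permutationTest(mp$A, mp$B, g, nPartitions = 300, seed = 5000 + i)
    any(vapply(clusters(r), function(cl) cl$mcP < 0.05, logical(1)))
  }, logical(1))
  # dataset-level false-positive rate compatible with alpha = 0.05
  expect_lte(mean(hits), 0.15)
})
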