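test_that("surrogate heartbeats preserve counts, span, and determinism", {
  rec <- quietRecording(4, 50000)
  hb <- HeartbeatSeries(seq(200, 49000, by = 200), 250, source = "DETECTED")
  ss <- makeSurrogateHeartbeats(rec, hb, nSurrogates = 100, seed = 5)
  expect_length(ss, 100)
  for (s in ss[1:10]) {
    expect_length(rpeaks(s), length(rpeaks(hb)))
    expect_true(all(rpeaks(s) >= 0 & rpeaks(s) < 50000))
    expect_true(all(diff(rpeaks(s)) > 0))
    expect_identical(s@source, "SURROGATE")
  }
  ss2 <- makeSurrogateHeartbeats(rec, hb, nSurrogates = 100, seed = 5)
  expect_identical(rpeaks(ss2[[37]]), rpeaks(ss[[37]]))
  # pooled timings uniform over the recording span
  pooled <- unlist(lapply(ss, rpeaks))
  ks <- suppressWarnings(ks.test(pooled / 50000, "punif"))
  expect_gt(ks$p.value, 0.01)
})

mkResult <- function(clusters) {
  new("ClusterResult", z = matrix(0, 1, 1), p = matrix(1, 1, 1),
      clusters = clusters, permDistribution = numeric(10), nPartitions = 10,
      exhaustive = FALSE, seed = 1, combinedEffects = data.frame(), fs = 250,
      channelNames = "a")
}
mkCl <- function(stat, nCh, sign = "+") {
  list(members = cbind(channel = seq_len(nCh), time = rep(1, nCh)), sign = sign,
       nChannels = nCh, size = nCh, stat = stat, latencyMs = c(0, 4), mcP = 0.01)
}

test_that("surrogate Monte Carlo p is the conjunction exceedance proportion", {
  observed <- mkResult(list(mkCl(3.0, 20)))
  # 3 of 100 surrogates exceed in both statistic and channel extent -> p = 0.03
  surr <- c(lapply(1:3, function(i) mkResult(list(mkCl(3.5, 25)))),
            lapply(1:47, function(i) mkResult(list(mkCl(3.5, 10)))),   # too few channels
            lapply(1:30, function(i) mkResult(list(mkCl(2.0, 40)))),   # stat too small
            lapply(1:20, function(i) mkResult(list())))                # no clusters
  res <- surrogateMcP(observed, surr)
  expect_equal(res$p, 0.03)
  # zero exceedances
  res0 <- surrogateMcP(observed, lapply(1:100, function(i) mkResult(list())))
  expect_equal(res0$p, 0)
  # observed weaker than every surrogate
  res1 <- surrogateMcP(observed, lapply(1:50, function(i) mkResult(list(mkCl(4, 30)))))
  expect_equal(res1$p, 1)
  # ties count as exceedances; opposite-sign surrogate clusters do not
  resT <- surrogateMcP(observed, list(mkResult(list(mkCl(3.0, 20))),
                                      mkResult(list(mkCl(5, 50, sign = "-")))))
  expect_equal(resT$p, 0.5)
  # the point-count size measure remains available
  resP <- surrogateMcP(observed, surr, sizeOn = "points")
  expect_equal(resP$p, 0.03)
  expect_error(surrogateMcP(mkResult(list()), surr), "no clusters")
})

test_that("surrogate analysis is deterministic and detects heartbeat locking", {
  cfg <- simConfig(layout_type = "grid", n_channels = 36, trials_per_block = 12,
                   erp_local_amp = 0, erp_global_amp = 0)
  groups <- rep(c("MCS", "UWS"), each = 5)
  subj <- lapply(seq_along(groups), function(i) {
    s <- simulateSubject(cfg, groups[i], seed = deriveSeed(500, "x", i))
    hb <- detectRPeaks(s$truth$ecg, 250)
    list(recording = s$recording, hb = hb)
  })
  g <- buildNeighborGraph(herclust:::simLayout(cfg), 4)
  r1 <- surrogateAnalysis(subj, groups, "LOCAL", g, nSurrogates = 8,
                          nPartitions = 120, seed = 77)
  r2 <- surrogateAnalysis(subj, groups, "LOCAL", g, nSurrogates = 8,
                          nPartitions = 120, seed = 77)
  expect_identical(r1$p, r2$p)
  expect_identical(permDistribution(r1$observed), permDistribution(r2$observed))
  expect_true(is.na(r1$p) || (r1$p >= 0 && r1$p <= 1))
})
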