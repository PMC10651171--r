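mkRec <- function(eeg, fs = 250, layout = NULL) {
  if (is.null(layout)) layout <- gridLayout(ceiling(nrow(eeg) / 2), 2)
  layout <- SensorLayout(channelNames(layout)[seq_len(nrow(eeg))],
                         sensorPositions(layout)[seq_len(nrow(eeg)), , drop = FALSE])
  Recording(eeg, fs, layout)
}

test_that("band-pass filter passes the band and removes DC and high frequencies", {
  fs <- 250; t <- (0:(8 * fs - 1)) / fs
  mid <- (2 * fs):(6 * fs)   # away from filter transients
  for (mode in c("iir", "fir")) {
    rec <- mkRec(rbind(rep(1, length(t)), sin(2 * pi * 10 * t), sin(2 * pi * 50 * t)))
    out <- eegData(bandpassFilter(rec, 1, 25, mode = mode))
    expect_lt(max(abs(out[1, mid])), 1e-3)                 # DC gone
    expect_gt(max(abs(out[2, mid])), 0.95)                 # 10 Hz passed
    expect_lt(max(abs(out[2, mid])), 1.05)
    expect_lt(max(abs(out[3, mid])), 0.1)                  # 50 Hz attenuated
  }
  expect_error(bandpassFilter(mkRec(matrix(0, 2, 100), fs = 40), 1, 25), "Nyquist")
})

test_that("filtering is linear", {
  set.seed(3)
  x <- matrix(rnorm(2 * 2000), 2, 2000)
  y <- matrix(rnorm(2 * 2000), 2, 2000)
  fx <- eegData(bandpassFilter(mkRec(x)))
  fy <- eegData(bandpassFilter(mkRec(y)))
  fxy <- eegData(bandpassFilter(mkRec(2 * x - 3 * y)))
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-6)
})

test_that("iterative z-score channel rejection removes outliers and reaches a fixpoint", {
  set.seed(4)
  base <- matrix(rnorm(32 * 2000), 32, 2000)
  # identical channels: nothing rejected
  same <- mkRec(matrix(1, 4, 100) * sin(2 * pi * (1:100) / 25)[col(matrix(1, 4, 100))])
  expect_length(rejectChannelsZscore(same)$report$rejected_channels_zscore, 0)
  # one channel scaled x50: exactly that channel, iteration 1
  x <- base; x[7, ] <- x[7, ] * 50
  rr <- rejectChannelsZscore(mkRec(x, layout = gridLayout(8, 4)))
  expect_identical(rr$report$rejected_channels_zscore, channelNames(mkRec(x, layout = gridLayout(8, 4)))[7])
  # two scaled channels: both rejected (possibly over iterations)
  y <- base; y[3, ] <- y[3, ] * 50; y[11, ] <- y[11, ] * 20
  rr2 <- rejectChannelsZscore(mkRec(y, layout = gridLayout(8, 4)))
  expect_setequal(rr2$report$rejected_channels_zscore,
                  channelNames(mkRec(y, layout = gridLayout(8, 4)))[c(3, 11)])
  # fixpoint: rejecting again removes nothing
  rr3 <- rejectChannelsZscore(rr2$recording)
  expect_length(rr3$report$rejected_channels_zscore, 0)
})

test_that("ICA recovers the cardiac component and cleans the artifact", {
  cfg <- simConfig(n_channels = 24, trials_per_block = 25, n_blocks_xx = 1,
                   n_blocks_xy = 1)
  s <- simulateSubject(cfg, "MCS", seed = 21)
  ic <- extractIcaEcg(s$recording, seed = 31)
  hb <- detectRPeaks(ic$ecg, 250)
  truth <- s$truth$true_rpeak_samples
  hit <- vapply(truth, function(p) min(abs(p - rpeaks(hb))) <= 1, logical(1))
  expect_gte(mean(hit), 0.99)
  # cleaned data: correlation with the QRS train drops by >= 80% on the most
  # affected channel
  corWith <- function(eeg) max(abs(apply(eeg, 1, cor, y = s$truth$ecg)))
  expect_lt(corWith(eegData(ic$recording)), 0.2 * corWith(eegData(s$recording)))
  # zero cardiac mixing: selection error advising an external ECG
  cfg0 <- simConfig(n_channels = 24, trials_per_block = 25, n_blocks_xx = 1,
                    n_blocks_xy = 1, artifact_gain = 0)
  s0 <- simulateSubject(cfg0, "MCS", seed = 22)
  expect_error(extractIcaEcg(s0$recording, seed = 31), "external ECG")
})

test_that("weighted-by-distance correlation drives spline interpolation", {
  # exact correlations by construction: centred orthonormal u, v
  n <- 1000
  u <- sin(2 * pi * (1:n) / 50); u <- (u - mean(u)) / sqrt(sum((u - mean(u))^2))
  v <- cos(2 * pi * (1:n) / 50); v <- (v - mean(v)) / sqrt(sum((v - mean(v))^2))
  stopifnot(abs(sum(u * v)) < 1e-10)
  # channel at origin with neighbours at 2 cm (corr 0.9) and 4 cm (corr 0.3):
  # weighted mean = (0.9/2 + 0.3/4) / (1/2 + 1/4) = 0.70 < 0.80 -> interpolated
  # (a fourth, isolated channel keeps the flagged set at half the montage)
  lay <- SensorLayout(c("c0", "n2", "n4", "far"),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0), c(20, 0, 0)))
  x0 <- u
  x2 <- 0.9 * u + sqrt(1 - 0.81) * v
  x4 <- 0.3 * u + sqrt(1 - 0.09) * v
  rec <- Recording(rbind(x0, x2, x4, v) * 10, 250, lay)
  g <- buildNeighborGraph(lay, 4)
  ir <- interpolateLowCorrelationChannels(rec, g)
  expect_equal(unname(ir$report$weighted_correlations["c0"]), 0.70, tolerance = 1e-10)
  expect_true("c0" %in% ir$report$interpolated_channels)
  # channel identical to all its neighbours: weighted correlation 1, retained
  lay2 <- gridLayout(3, 1, 3)
  sig <- sin(2 * pi * (1:n) / 40)
  rec2 <- Recording(rbind(sig, sig, sig), 250, lay2)
  ir2 <- interpolateLowCorrelationChannels(rec2, buildNeighborGraph(lay2, 4))
  expect_length(ir2$report$interpolated_channels, 0)
  # independent-noise channel among coherent neighbours is interpolated and
  # becomes similar to them
  set.seed(9)
  lay3 <- gridLayout(3, 3, 3)
  common <- rnorm(n)
  sigs <- t(vapply(1:9, function(i) common + rnorm(n, sd = 0.05), numeric(n)))
  sigs[5, ] <- 0.6 * common + rnorm(n)   # decorrelated centre, neighbours stay coherent
  rec3 <- Recording(sigs, 250, lay3)
  ir3 <- interpolateLowCorrelationChannels(rec3, buildNeighborGraph(lay3, 4))
  expect_true(channelNames(lay3)[5] %in% ir3$report$interpolated_channels)
  expect_gt(cor(eegData(ir3$recording)[5, ], common), 0.9)
})

test_that("common-average re-referencing is idempotent and subsets in order", {
  set.seed(5)
  rec <- mkRec(matrix(rnorm(8 * 500, mean = 3), 8, 500), layout = gridLayout(4, 2))
  rr <- rereferenceAndSubset(rec)
  expect_lt(max(abs(colMeans(eegData(rr)))), 1e-9)
  rr2 <- rereferenceAndSubset(rr)
  expect_lt(max(abs(eegData(rr2) - eegData(rr))), 1e-9)
  sub <- rev(channelNames(rec))[1:4]
  rs <- rereferenceAndSubset(rec, sub)
  expect_identical(channelNames(rs), sub)
  expect_equal(nrow(eegData(rs)), 4)
  expect_error(rereferenceAndSubset(rec, c("nope", sub)), "nope")
})
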