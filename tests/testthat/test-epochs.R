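# hand-enumerated toy streams exercising every rejection rule exactly

test_that("stimulus epoching applies the amplitude and edge rules", {
  ev <- rbind(toyTrial(500, 1, "LSGS"), toyTrial(1200, 2, "LDGD"),
              toyTrial(3900, 3, "LDGS", "XY"))   # epoch would end at 4150 > 4000
  rec <- quietRecording(4, 4000, events = ev)
  eeg <- eegData(rec)
  eeg[2, 520] <- 350   # one 350 uV sample inside trial 1's epoch
  rec@eeg <- eeg
  ep <- epochStimulus(rec)
  rl <- rejectionLog(ep)
  expect_identical(rl$accepted, c(FALSE, TRUE, FALSE))
  expect_identical(rl$reason[!rl$accepted], c("AMP300", "EDGE"))
  expect_identical(epochConditions(ep), "LDGD")
  # all-quiet recording: every trial accepted
  ev80 <- do.call(rbind, lapply(1:8, function(i) toyTrial(300 + i * 400, i, "LSGS")))
  ep80 <- epochStimulus(quietRecording(4, 4000, events = ev80))
  expect_equal(dim(epochData(ep80))[1], 8)
  expect_error(epochStimulus(quietRecording(4, 900, events = toyTrial(850, 1, "LSGS"))),
               "zero surviving")
})

test_that("heartbeat-locked epoching applies the guard, IBI, ectopic and edge rules", {
  fs <- 250
  # trial A: 5th sound at 1000, nearest peak at 997 (12 ms) -> STIM20MS
  # trial B: 5th sound at 2000, lock 2100 whose following IBI is 400 ms -> IBI500
  # trial C: 5th sound at 3000, peaks 2900/3100 clean -> accepted, lock 3100
  ev <- rbind(toyTrial(1000, 1, "LSGS"), toyTrial(2000, 2, "LDGD"),
              toyTrial(3000, 3, "LDGS", "XY"))
  peaks <- c(600, 997, 1180, 1550, 1750, 2100, 2200, 2400, 2900, 3100, 3500)
  rec <- quietRecording(4, 4000, events = ev)
  hb <- HeartbeatSeries(peaks, fs, source = "DETECTED")
  ep <- epochHeartbeatPostStimulus(rec, hb)
  rl <- rejectionLog(ep)
  expect_identical(rl$reason[1], "STIM20MS")      # |1000 - 997| * 4 = 12 ms < 20
  expect_identical(rl$reason[2], "IBI500")        # 2200 - 2100 = 100 smp = 400 ms
  expect_identical(rl$accepted, c(FALSE, FALSE, TRUE))
  expect_identical(rl$lock_sample[3], 3100)
  # stimulus-to-lock distance 400 ms >= 20 ms guard
  expect_identical(epochConditions(ep), "LDGS")
})

test_that("ectopic and amplitude rules reject heartbeat-locked epochs", {
  fs <- 250
  # ECTOPIC: the lock peak of trial A bounds a flagged interval
  ev <- rbind(toyTrial(1000, 1, "LSGS"), toyTrial(2000, 2, "LDGD"))
  rec <- quietRecording(4, 4000, events = ev)
  peaks <- c(400, 900, 1150, 1500, 2150, 2600, 3000)
  flags <- c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)   # 900 -> 1150 flagged
  hb <- HeartbeatSeries(peaks, fs, source = "DETECTED", ectopicFlags = flags)
  ep <- epochHeartbeatPostStimulus(rec, hb)
  rl <- rejectionLog(ep)
  expect_identical(rl$reason[1], "ECTOPIC")
  expect_identical(rl$accepted, c(FALSE, TRUE))
  # AMP300: a 400 uV sample inside trial A's epoch
  rec2 <- quietRecording(4, 4000, events = ev)
  eeg <- eegData(rec2); eeg[1, 1210] <- 400; rec2@eeg <- eeg
  hb2 <- HeartbeatSeries(c(400, 900, 1200, 1600, 2400, 2900, 3400), fs, "DETECTED")
  ep2 <- epochHeartbeatPostStimulus(rec2, hb2)
  expect_identical(rejectionLog(ep2)$reason[1], "AMP300")
  expect_identical(rejectionLog(ep2)$accepted, c(FALSE, TRUE))
})

test_that("whole-protocol heartbeat epoching counts and rejects as specified", {
  fs <- 250
  rec <- quietRecording(4, 100000)
  peaks <- seq(500, 98000, by = 200)   # clean 800 ms rhythm
  hb <- HeartbeatSeries(peaks, fs, source = "DETECTED")
  ep <- epochAllHeartbeats(rec, hb)
  expect_equal(dim(epochData(ep))[1], length(peaks))
  expect_true(all(epochConditions(ep) == "NONE"))
  # a tachycardic run (IBI 450 ms) is fully rejected IBI500
  p2 <- sort(c(peaks, peaks[100:110] + round(0.45 * 250)))
  hb2 <- HeartbeatSeries(p2, fs, source = "DETECTED")
  ep2 <- epochAllHeartbeats(rec, hb2)
  rl2 <- rejectionLog(ep2)
  expect_true(all(rl2$reason[!rl2$accepted] == "IBI500"))
  expect_gt(sum(!rl2$accepted), 20)
  # determinism of the rejection log
  ep3 <- epochAllHeartbeats(rec, hb2)
  expect_identical(rejectionLog(ep3), rl2)
  # conservation: accepted + rejected = candidates
  expect_equal(sum(rl2$accepted) + sum(!rl2$accepted), length(p2))
})

test_that("subject contrasts follow pooled-mean arithmetic", {
  mkEp <- function(values, conds) {
    nEp <- length(conds)
    data <- array(rep(values, each = 1), dim = c(nEp, 2, 3))
    for (i in seq_len(nEp)) data[i, , ] <- values[i]
    new("EpochSet", data = data, lock = "STIMULUS_5TH", fs = 250,
        epochLengthMs = 12, conditions = conds, channelNames = c("a", "b"),
        rejectionLog = data.frame(candidate = seq_len(nEp),
                                  lock_sample = seq_len(nEp),
                                  accepted = rep(TRUE, nEp),
                                  reason = NA_character_))
  }
  ep <- mkEp(c(2, 4, 0, -2), c("LDGS", "LDGD", "LSGS", "LSGD"))
  expect_true(all(effectMatrix(subjectEffect(ep, "LOCAL")) == 4))
  expect_true(all(abs(effectMatrix(subjectEffect(ep, "GLOBAL"))) < 1e-12))
  # unequal counts: 30 LDGS at +2 and 10 LDGD at +4 -> deviant pooled mean 2.5
  ep2 <- mkEp(c(rep(2, 30), rep(4, 10), rep(0, 20)),
              c(rep("LDGS", 30), rep("LDGD", 10), rep("LSGS", 20)))
  expect_true(all(abs(effectMatrix(subjectEffect(ep2, "LOCAL")) - 2.5) < 1e-12))
  # means-pooling alternative: (2 + 4)/2 - 0 = 3
  expect_true(all(abs(effectMatrix(subjectEffect(ep2, "LOCAL", pooling = "means")) - 3) < 1e-12))
  # contrast linearity: adding c to deviants shifts the map by c
  ep3 <- mkEp(c(2 + 7, 4 + 7, 0, -2), c("LDGS", "LDGD", "LSGS", "LSGD"))
  expect_true(all(abs(effectMatrix(subjectEffect(ep3, "LOCAL")) -
                        (effectMatrix(subjectEffect(ep, "LOCAL")) + 7)) < 1e-12))
  # missing side errors with the missing condition names
  ep4 <- mkEp(c(1, 2), c("LDGS", "LDGD"))
  expect_error(subjectEffect(ep4, "LOCAL"), "LSGS")
  # identical constant epochs -> zero map
  ep5 <- mkEp(rep(3, 4), c("LDGS", "LSGS", "LSGD", "LDGD"))
  expect_true(all(effectMatrix(subjectEffect(ep5, "LOCAL")) == 0))
})

test_that("whole-protocol HER summary computes unbiased variance", {
  data <- array(0, dim = c(4, 2, 3))
  data[, 1, 1] <- c(1, -1, 1, -1)
  ep <- new("EpochSet", data = data, lock = "RPEAK_ALL", fs = 250,
            epochLengthMs = 12, conditions = rep("NONE", 4),
            channelNames = c("a", "b"),
            rejectionLog = data.frame(candidate = 1:4, lock_sample = 1:4,
                                      accepted = rep(TRUE, 4), reason = NA_character_))
  hs <- herSummaryWholeProtocol(ep)
  expect_equal(hs$variance[1, 1], 4 / 3)
  expect_equal(hs$mean[1, 1], 0)
  expect_true(all(hs$variance[-1] == 0))
})

test_that("epoch sets round-trip through their directory serialisation", {
  ev <- do.call(rbind, lapply(1:4, function(i)
    toyTrial(300 + i * 400, i, c("LSGS", "LDGD", "LDGS", "LSGD")[i])))
  rec <- quietRecording(4, 4000, events = ev)
  rec@eeg <- matrix(rnorm(4 * 4000), 4, 4000)
  ep <- epochStimulus(rec)
  d <- withr::local_tempdir()
  saveEpochSet(ep, d)
  ep2 <- loadEpochSet(d)
  expect_identical(epochData(ep2), epochData(ep))
  expect_identical(epochConditions(ep2), epochConditions(ep))
  expect_identical(rejectionLog(ep2)$accepted, rejectionLog(ep)$accepted)
})

test_that("latency-balance tests match closed-form rank statistics", {
  mk <- function(vals, group) do.call(rbind, lapply(seq_along(vals), function(i)
    data.frame(subject = paste0(group, i), group = group,
               condition = c("local_standard", "local_deviant",
                             "global_standard", "global_deviant"),
               latency_ms = vals[i])))
  lat <- rbind(mk(c(100, 110, 120), "MCS"), mk(c(300, 310, 320), "UWS"))
  res <- latencyBalanceTest(lat)
  expect_equal(abs(res$Z), rep(4.5 / sqrt(5.25), 4), tolerance = 1e-4)  # 1.964
  same <- rbind(mk(c(100, 110, 120), "MCS"), mk(c(100, 110, 120), "UWS"))
  res2 <- latencyBalanceTest(same)
  expect_true(all(res2$Z == 0) && all(res2$p == 1))
  expect_error(latencyBalanceTest(mk(c(1, 2), "MCS")), "at least 2")
})
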