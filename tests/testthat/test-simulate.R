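timing <- list(fs = 250, tone_duration_ms = 50, soa_ms = 150,
               iti_range_ms = c(1350, 1650))

test_that("event streams follow block semantics and timing", {
  for (bt in c("XX", "XY")) {
    es <- generateEventStream(bt, 100, 0.2, timing, seed = 4)
    ev <- es$events
    expect_equal(nrow(ev), 500)
    freqCond <- if (bt == "XX") "LSGS" else "LDGS"
    rareCond <- if (bt == "XX") "LDGD" else "LSGD"
    perTrial <- tapply(ev$condition, ev$trial_id, unique)
    expect_equal(sum(perTrial == rareCond), 20)   # round(0.2 * 100)
    expect_true(all(perTrial %in% c(freqCond, rareCond)))
    # within-trial onsets one SOA apart (single-sample quantisation);
    # 5th sound exactly 600 ms after the 1st
    for (tid in unique(ev$trial_id)) {
      on <- ev$onset_sample[ev$trial_id == tid]
      expect_true(all(diff(on) %in% c(37L, 38L)))  # 150 ms = 37.5 samples
      expect_equal((on[5] - on[1]) * 4, 600)
    }
    # inter-trial gap: 5th onset + tone to next 1st onset within the ITI range
    fifth <- ev$onset_sample[ev$sound_index == 5]
    first <- ev$onset_sample[ev$sound_index == 1]
    gaps <- (first[-1] - fifth[-length(fifth)]) * 4 - 50
    expect_true(all(gaps >= 1350 - 4 & gaps <= 1650 + 4))
  }
  expect_error(generateEventStream("XX", 10, 1.2, timing), "rareFraction")
})

test_that("simulated cardiac traces have the requested beat structure", {
  z <- simulateCardiac(10, 250, 800, 0, seed = 1)
  expect_identical(unique(diff(z$rpeaks)), 200)    # exactly 800 ms at 250 Hz
  z2 <- simulateCardiac(10, 250, 1000, 0, seed = 1)
  expect_true(abs(length(z2$rpeaks) - 10) <= 1)
  # determinism
  z3 <- simulateCardiac(30, 250, 800, 60, seed = 7)
  z4 <- simulateCardiac(30, 250, 800, 60, seed = 7)
  expect_identical(z3$ecg, z4$ecg)
  expect_identical(z3$rpeaks, z4$rpeaks)
  # truncation floor: no two peaks closer than the floor
  z5 <- simulateCardiac(60, 250, 600, 400, seed = 2, rrFloorMs = 250)
  expect_true(min(diff(z5$rpeaks)) >= 250 * 250 / 1000 - 1)
  # peaks are the global maxima of their template instances
  expect_true(all(z$ecg[z$rpeaks + 1] == 1))
  expect_error(simulateCardiac(10, 250, 800, -1), "non-negative")
})

test_that("subject simulation is deterministic and respects null construction", {
  cfg <- simConfig(n_channels = 16, trials_per_block = 6, n_blocks_xx = 1,
                   n_blocks_xy = 1)
  s1 <- simulateSubject(cfg, "MCS", seed = 5)
  s2 <- simulateSubject(cfg, "MCS", seed = 5)
  expect_identical(eegData(s1$recording), eegData(s2$recording))
  expect_identical(s1$truth$true_rpeak_samples, s2$truth$true_rpeak_samples)
  expect_error(simulateSubject(cfg, "UNKNOWN", seed = 1), "group")
  # all effect amplitudes zero: EEG is noise + cardiac artifact only, so the
  # deviant-minus-standard maps have expectation ~ 0
  cfg0 <- simConfig(n_channels = 16, trials_per_block = 40, n_blocks_xx = 1,
                    n_blocks_xy = 1, erp_local_amp = 0, erp_global_amp = 0,
                    her_local_amp = 0, her_global_amp = 0, her_variability_sd = 0)
  s0 <- simulateSubject(cfg0, "MCS", seed = 9)
  m <- herclust:::fastErpMaps(s0$recording)
  expect_lt(abs(mean(m$LOCAL)), 0.5)
  expect_lt(abs(mean(m$GLOBAL)), 0.5)
})

test_that("planted heartbeat-locked amplitude is recovered at the window centre", {
  cfg <- simConfig(n_channels = 16, trials_per_block = 40, n_blocks_xx = 2,
                   n_blocks_xy = 2, noise_sd_uv = 1, artifact_gain = 0,
                   her_variability_sd = 0, her_local_amp = 5, her_global_amp = 0,
                   erp_local_amp = 0, erp_global_amp = 0,
                   uws_erp_local_factor = 0, uws_her_local_factor = 0,
                   layout_type = "grid")
  s <- simulateSubject(cfg, "MCS", seed = 3)
  hb <- HeartbeatSeries(s$truth$true_rpeak_samples, 250, source = "TRUE")
  maps <- herclust:::fastHerMaps(s$recording, hb)
  lay <- herclust:::simLayout(cfg)
  effCh <- match(s$truth$effect_channels, channelNames(lay))
  # peak of the planted bump inside the window, at the bump's unit-peak sample
  win <- 100:104   # 1-based map columns covering 400-412 ms and a margin
  expect_lt(abs(max(colMeans(maps$LOCAL[effCh, win])) - 5), 0.5)
})

test_that("cohorts are deterministic with matching manifests and block counts", {
  cfg <- simConfig(n_mcs = 3, n_uws = 2, n_control = 1, n_channels = 16,
                   trials_per_block = 4)
  co <- simulateCohort(cfg)
  expect_identical(co$manifest$group, c(rep("MCS", 3), rep("UWS", 2), "CONTROL"))
  expect_length(co$subjects, 6)
  # controls complete one XX and one XY block (half the patient block count)
  nb <- function(s) length(unique(auditoryEvents(s$recording)$block_type))
  patientTrials <- max(auditoryEvents(co$subjects[[1]]$recording)$trial_id)
  controlTrials <- max(auditoryEvents(co$subjects[[6]]$recording)$trial_id)
  expect_equal(controlTrials * 2, patientTrials)
  co2 <- simulateCohort(cfg)
  expect_identical(eegData(co2$subjects[[2]]$recording),
                   eegData(co$subjects[[2]]$recording))
  expect_error(simulateCohort(simConfig(n_mcs = 0, n_uws = 0, n_control = 0)),
               "zero")
})

test_that("written cohorts round-trip through the manifest files", {
  d <- withr::local_tempdir()
  cfg <- simConfig(n_mcs = 1, n_uws = 1, n_control = 0, n_channels = 8,
                   trials_per_block = 3, layout_type = "grid")
  co <- simulateCohort(cfg, outDir = d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  rec <- loadRecording(co$manifest$eeg[1], co$manifest$events[1],
                       co$manifest$layout[1], group = co$manifest$group[1])
  expect_equal(nrow(eegData(rec)), 8)
  expect_gt(nrow(auditoryEvents(rec)), 0)
  # byte-identical sidecars across two runs with the same master seed
  d2 <- withr::local_tempdir()
  simulateCohort(cfg, outDir = d2)
  expect_identical(readLines(co$manifest$truth[1]),
                   readLines(file.path(d2, basename(co$manifest$truth[1]))))
})
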