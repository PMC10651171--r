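test_that("EDF round trip preserves signals and events", {
  lay <- gridLayout(2, 2)
  ev <- rbind(toyTrial(500, 1, "LSGS"), toyTrial(1500, 2, "LDGD"))
  set.seed(1)
  eeg <- matrix(rnorm(4 * 2000, sd = 30), 4, 2000)
  rec <- Recording(eeg, 250, lay, ev, subjectId = "rt01", group = "MCS")
  d <- withr::local_tempdir()
  saveRecording(rec, file.path(d, "a.edf"), file.path(d, "a_ev.tsv"),
                file.path(d, "a_lay.tsv"))
  rec2 <- loadRecording(file.path(d, "a.edf"), file.path(d, "a_ev.tsv"),
                        file.path(d, "a_lay.tsv"))
  expect_identical(dim(eegData(rec2)), dim(eeg))
  # 16-bit scaling tolerance: range/65535 per channel
  tol <- max(apply(eeg, 1, function(x) diff(range(x)))) / 65535 * 1.01
  expect_lt(max(abs(eegData(rec2) - eeg)), tol)
  ev2 <- auditoryEvents(rec2)
  expect_identical(ev2$onset_sample, ev$onset_sample)
  expect_identical(ev2$condition, ev$condition)
  expect_identical(ev2$trial_id, ev$trial_id)
  expect_equal(samplingRate(rec2), 250)
})

test_that("loadRecording rejects inconsistent sidecars", {
  lay <- gridLayout(2, 2)
  rec <- quietRecording(4, 1000)
  d <- withr::local_tempdir()
  saveRecording(rec, file.path(d, "b.edf"), file.path(d, "b_ev.tsv"),
                file.path(d, "b_lay.tsv"))
  # events declaring a different sampling rate
  writeEvents(emptyEvents(), file.path(d, "bad_ev.tsv"), fs = 500)
  expect_error(loadRecording(file.path(d, "b.edf"), file.path(d, "bad_ev.tsv"),
                             file.path(d, "b_lay.tsv")), "mismatch")
  # events referencing a sample far beyond the recording
  ev <- toyTrial(1e9, 1, "LSGS")
  writeEvents(ev, file.path(d, "far_ev.tsv"), fs = 250)
  expect_error(loadRecording(file.path(d, "b.edf"), file.path(d, "far_ev.tsv"),
                             file.path(d, "b_lay.tsv")), "beyond")
  # layout not covering all EEG channels
  short <- readLayout(file.path(d, "b_lay.tsv"))
  writeLayout(SensorLayout(channelNames(short)[1:3],
                           sensorPositions(short)[1:3, ]),
              file.path(d, "short_lay.tsv"))
  expect_error(loadRecording(file.path(d, "b.edf"), file.path(d, "b_ev.tsv"),
                             file.path(d, "short_lay.tsv")), "cover")
})

test_that("BrainVision triplet reads back the written multiplexed data", {
  d <- withr::local_tempdir()
  nCh <- 3; n <- 500
  set.seed(2)
  eeg <- matrix(rnorm(nCh * n), nCh, n)
  writeLines(c("Brain Vision Data Exchange Header File Version 1.0",
               "[Common Infos]", "DataFile=x.eeg", "MarkerFile=x.vmrk",
               "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
               sprintf("NumberOfChannels=%d", nCh), "SamplingInterval=4000",
               "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
               "[Channel Infos]", "Ch1=C1,,1,uV", "Ch2=C2,,1,uV", "Ch3=C3,,1,uV"),
             file.path(d, "x.vhdr"))
  con <- file(file.path(d, "x.eeg"), "wb")
  writeBin(as.numeric(eeg), con, size = 4, endian = "little")
  close(con)
  bv <- readBrainVision(file.path(d, "x.vhdr"))
  expect_equal(bv$fs, 250)
  expect_identical(bv$labels, c("C1", "C2", "C3"))
  expect_lt(max(abs(bv$eeg - eeg)), 1e-6)
})

test_that("neighbour graph matches brute force and the inclusive boundary", {
  # 5x5 planar grid, 3 cm spacing, 4 cm threshold: inner channels have
  # exactly the 4 orthogonal neighbours (diagonal is 4.243 cm, outside)
  lay <- gridLayout(5, 5, 3)
  g <- buildNeighborGraph(lay, 4)
  inner <- which(sensorPositions(lay)[, 1] %in% c(3, 6, 9) &
                   sensorPositions(lay)[, 2] %in% c(3, 6, 9))
  expect_true(all(lengths(adjacency(g)[inner]) == 4))
  expect_identical(lapply(adjacency(g), as.integer), lapply(oracleNeighbors(lay, 4), as.integer))
  # boundary inclusive: two channels exactly 4.0 cm apart are adjacent
  lay2 <- SensorLayout(c("a", "b"), rbind(c(0, 0, 0), c(4, 0, 0)))
  g2 <- buildNeighborGraph(lay2, 4)
  expect_identical(as.integer(adjacency(g2)[[1]]), 2L)
  # single channel: empty adjacency
  g1 <- buildNeighborGraph(SensorLayout("a", rbind(c(0, 0, 0))), 4)
  expect_length(adjacency(g1)[[1]], 0)
  # random layouts equal brute force
  for (s in 1:3) {
    set.seed(s)
    layr <- SensorLayout(sprintf("r%02d", 1:20), matrix(runif(60, 0, 10), 20))
    gr <- buildNeighborGraph(layr, 4)
    expect_identical(lapply(adjacency(gr), as.integer),
                     lapply(oracleNeighbors(layr, 4), as.integer))
  }
})

test_that("saveTable round-trips values and encodes missing statistics as NA", {
  d <- withr::local_tempdir()
  df <- data.frame(stat = c(1.23456789012345e-7, -2.5, NaN),
                   label = c("a", "b", "c"), n = c(1L, 2L, 3L))
  p <- file.path(d, "t.tsv")
  saveTable(df, p)
  back <- readTableTsv(p)
  expect_identical(back$stat[1:2], df$stat[1:2])
  expect_true(is.na(back$stat[3]))
  expect_identical(back$n, df$n)
  expect_error(saveTable(data.frame(), file.path(d, "e.tsv")), "non-empty")
})
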