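#' @include AllClasses.R utils.R
NULL

padStr <- function(s, n) {
  s <- substr(s, 1, n)
  sprintf(paste0("%-", n, "s"), s)
}

numField <- function(x, n) padStr(formatC(x, format = "g", digits = n - 2, width = 1), n)

#' Write a Recording to an EDF file
#'
#' 16-bit EDF container with per-channel physical scaling taken from the
#' observed signal range (lossless to well below 0.1 microvolt for
#' microvolt-scale EEG). Records are 1 s long; a trailing partial record is
#' zero-padded and the true sample count is stored in the reserved header
#' field so that reading restores the exact length.
#'
#' @param recording a [Recording-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEdf <- function(recording, path) {
  eeg <- recording@eeg
  fs <- recording@fs
  if (abs(fs - round(fs)) > 1e-9) stop("writeEdf: sampling rate must be an integer number of Hz")
  fs <- as.integer(round(fs))
  nch <- nrow(eeg)
  ns <- ncol(eeg)
  nrec <- as.integer(ceiling(ns / fs))
  physMin <- apply(eeg, 1, min)
  physMax <- apply(eeg, 1, max)
  flat <- physMax - physMin < 1e-9
  physMax[flat] <- physMax[flat] + 1
  physMin[flat] <- physMin[flat] - 1
  digMin <- -32768; digMax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padStr("0", 8),
    padStr(recording@subjectId, 80),
    padStr(paste0("Startdate 01-JAN-2000 ", recording@group), 80),
    "01.01.00", "00.00.00",
    padStr(as.character(256 * (1 + nch)), 8),
    padStr(paste0("NS=", ns), 44),
    padStr(as.character(nrec), 8),
    padStr("1", 8),
    padStr(as.character(nch), 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- c(
    vapply(recording@layout@names, padStr, "", n = 16),
    rep(padStr("EEG", 80), nch),
    rep(padStr("uV", 8), nch),
    vapply(physMin, numField, "", n = 8),
    vapply(physMax, numField, "", n = 8),
    rep(padStr(as.character(digMin), 8), nch),
    rep(padStr(as.character(digMax), 8), nch),
    rep(padStr("", 80), nch),
    rep(padStr(as.character(fs), 8), nch),
    rep(padStr("", 32), nch)
  )
  writeChar(paste(fields, collapse = ""), con, eos = NULL)

  # re-read the truncated 8-char physical bounds so scaling matches the header
  physMinH <- as.numeric(vapply(physMin, numField, "", n = 8))
  physMaxH <- as.numeric(vapply(physMax, numField, "", n = 8))
  scale <- (digMax - digMin) / (physMaxH - physMinH)
  padded <- matrix(0, nch, nrec * fs)
  padded[, seq_len(ns)] <- eeg
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- vapply(seq_len(nch), function(ch) {
      as.integer(round((pmin(pmax(padded[ch, idx], physMinH[ch]), physMaxH[ch]) -
                          physMinH[ch]) * scale[ch]) + digMin)
    }, integer(fs))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return list with \code{eeg} (channels x samples matrix, physical units),
#'   \code{fs} (Hz), \code{labels} (channel names).
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (version != "0") stop("readEdf: malformed header (unsupported version field)")
  rd(80); rd(80); rd(8); rd(8)
  hdrBytes <- suppressWarnings(as.integer(rd(8)))
  reserved <- rd(44)
  nrec <- suppressWarnings(as.integer(rd(8)))
  recDur <- suppressWarnings(as.numeric(rd(8)))
  nch <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hdrBytes, nrec, recDur, nch)) || nch < 1)
    stop("readEdf: malformed header (non-numeric size fields)")
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)  # transducer
  for (i in seq_len(nch)) rd(8)   # unit
  physMin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)  # prefiltering
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1) stop("readEdf: heterogeneous sampling rates not supported")
  fs <- spr[1] / recDur
  eeg <- matrix(0, nch, nrec * spr[1])
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = nch * spr[1], size = 2, endian = "little")
    block <- matrix(block, nrow = spr[1], ncol = nch)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(nch)) {
      eeg[ch, idx] <- (block[, ch] - digMin[ch]) *
        (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch]) + physMin[ch]
    }
  }
  m <- regmatches(reserved, regexec("NS=([0-9]+)", reserved))[[1]]
  if (length(m) == 2) {
    ns <- as.integer(m[2])
    if (ns <= ncol(eeg)) eeg <- eeg[, seq_len(ns), drop = FALSE]
  }
  rownames(eeg) <- labels
  list(eeg = eeg, fs = fs, labels = labels)
}

#' Read a BrainVision recording (.vhdr + binary .eeg)
#'
#' Minimal reader for the BrainVision triplet: multiplexed binary data in
#' INT_16 (scaled by the per-channel resolution) or IEEE_FLOAT_32 format.
#'
#' @param vhdrPath path to the .vhdr header file.
#' @return list with \code{eeg}, \code{fs}, \code{labels} as [readEdf()].
#' @export
readBrainVision <- function(vhdrPath) {
  lines <- readLines(vhdrPath, warn = FALSE)
  getVal <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) stop("readBrainVision: malformed header, missing ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  dataFile <- getVal("DataFile")
  fmt <- getVal("DataFormat")
  if (toupper(fmt) != "BINARY") stop("readBrainVision: only BINARY DataFormat supported")
  orient <- getVal("DataOrientation")
  if (toupper(orient) != "MULTIPLEXED") stop("readBrainVision: only MULTIPLEXED orientation supported")
  nch <- as.integer(getVal("NumberOfChannels"))
  sampInt <- as.numeric(getVal("SamplingInterval"))  # microseconds
  fs <- 1e6 / sampInt
  binFmt <- toupper(getVal("BinaryFormat"))
  chLines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(chLines) < nch) stop("readBrainVision: channel info incomplete")
  parts <- strsplit(sub("^Ch[0-9]+=", "", chLines[seq_len(nch)]), ",")
  labels <- vapply(parts, `[`, "", 1)
  resolution <- vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[3])); if (is.na(r)) 1 else r
  }, 0)
  binPath <- file.path(dirname(vhdrPath), dataFile)
  if (!file.exists(binPath)) stop("readBrainVision: data file not found: ", binPath)
  sz <- file.info(binPath)$size
  con <- file(binPath, "rb")
  on.exit(close(con))
  if (binFmt == "INT_16") {
    raw <- readBin(con, "integer", n = sz / 2, size = 2, endian = "little")
    eeg <- matrix(raw, nrow = nch) * resolution
  } else if (binFmt == "IEEE_FLOAT_32") {
    raw <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
    eeg <- matrix(raw, nrow = nch) * resolution
  } else stop("readBrainVision: unsupported BinaryFormat ", binFmt)
  rownames(eeg) <- labels
  list(eeg = eeg, fs = fs, labels = labels)
}

#' Write / read the auditory event sidecar (TSV)
#'
#' Tab-separated with header columns onset_sample, trial_id, sound_index,
#' block_type, condition. A leading comment line records the sampling rate for
#' cross-file consistency checking.
#'
#' @param events event data.frame.
#' @param path file path.
#' @param fs sampling rate recorded in the sidecar header (Hz), optional.
#' @return invisibly, the path.
#' @export
writeEvents <- function(events, path, fs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(fs)) writeLines(sprintf("# sampling_rate_hz: %g", fs), con)
  write.table(events, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @return \code{readEvents}: list with \code{events} data.frame and \code{fs}
#'   (NA when the sidecar does not declare one).
#' @export
readEvents <- function(path) {
  first <- readLines(path, n = 1)
  fs <- NA_real_
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("sampling_rate_hz:\\s*([0-9.]+)", first))[[1]]
    if (length(m) == 2) fs <- as.numeric(m[2])
  }
  ev <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("onset_sample", "trial_id", "sound_index", "block_type", "condition")
  if (!all(need %in% names(ev)))
    stop("readEvents: missing columns: ", paste(setdiff(need, names(ev)), collapse = ", "))
  list(events = ev[, need], fs = fs)
}

#' Write / read a sensor layout table (TSV: name, x_cm, y_cm, z_cm)
#' @param layout a [SensorLayout-class].
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeLayout <- function(layout, path) {
  df <- data.frame(name = layout@names,
                   x_cm = layout@positions[, 1],
                   y_cm = layout@positions[, 2],
                   z_cm = layout@positions[, 3])
  saveTable(df, path)
}

#' @rdname writeLayout
#' @return \code{readLayout}: a [SensorLayout-class].
#' @export
readLayout <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("name", "x_cm", "y_cm", "z_cm")
  if (!all(need %in% names(df)))
    stop("readLayout: missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  SensorLayout(df$name, as.matrix(df[, c("x_cm", "y_cm", "z_cm")]))
}

#' Load a validated Recording from disk
#'
#' Reads the EEG container (EDF or BrainVision .vhdr), the event sidecar and
#' the layout table, cross-checks declared sampling rates and channel
#' coverage, and returns a validated [Recording-class]. Channels present in
#' the EEG but absent from the layout are an error, never silently dropped.
#'
#' @param eegPath EDF (.edf) or BrainVision header (.vhdr) path.
#' @param eventsPath events TSV path.
#' @param layoutPath layout TSV path.
#' @param subjectId subject identifier (default from file name).
#' @param group diagnostic group label.
#' @return A [Recording-class].
#' @export
loadRecording <- function(eegPath, eventsPath, layoutPath,
                          subjectId = sub("\\.[^.]+$", "", basename(eegPath)),
                          group = "UNKNOWN") {
  for (p in c(eegPath, eventsPath, layoutPath))
    if (!file.exists(p)) stop("loadRecording: file not found: ", p)
  raw <- if (grepl("\\.vhdr$", eegPath, ignore.case = TRUE)) readBrainVision(eegPath)
         else readEdf(eegPath)
  evl <- readEvents(eventsPath)
  if (!is.na(evl$fs) && abs(evl$fs - raw$fs) > 1e-6)
    stop(sprintf("loadRecording: sampling-rate mismatch (EEG %g Hz, events sidecar %g Hz)",
                 raw$fs, evl$fs))
  layout <- readLayout(layoutPath)
  missing <- setdiff(raw$labels, layout@names)
  if (length(missing))
    stop("loadRecording: layout does not cover EEG channels: ", paste(missing, collapse = ", "))
  ord <- match(raw$labels, layout@names)
  layout <- SensorLayout(layout@names[ord], layout@positions[ord, , drop = FALSE])
  if (nrow(evl$events) && any(evl$events$onset_sample >= ncol(raw$eeg)))
    stop("loadRecording: event onset beyond the end of the recording (consistency error)")
  logMsg("core_io", "loaded ", subjectId, ": ", nrow(raw$eeg), " channels x ",
         ncol(raw$eeg), " samples")
  Recording(raw$eeg, raw$fs, layout, evl$events, subjectId = subjectId, group = group)
}

#' Save a Recording (EDF + events TSV + layout TSV)
#' @param recording a [Recording-class].
#' @param eegPath,eventsPath,layoutPath output paths.
#' @return invisibly, the EEG path.
#' @export
saveRecording <- function(recording, eegPath, eventsPath, layoutPath) {
  writeEdf(recording, eegPath)
  writeEvents(recording@events, eventsPath, fs = recording@fs)
  writeLayout(recording@layout, layoutPath)
  invisible(eegPath)
}

#' Write a rectangular results table as TSV with full numeric precision
#'
#' NaN/NA statistics are serialised as the explicit token "NA" and re-read as
#' missing values.
#'
#' @param records non-empty data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
saveTable <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0 || ncol(records) == 0)
    stop("saveTable: records must be a non-empty data.frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- formatC(out[[j]], format = "g", digits = 17)
      v[!is.finite(out[[j]]) & !is.na(out[[j]])] <- as.character(out[[j]][!is.finite(out[[j]]) & !is.na(out[[j]])])
      v[is.na(out[[j]])] <- "NA"
      out[[j]] <- v
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV written by [saveTable()]
#' @param path file path.
#' @return data.frame.
#' @export
readTableTsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE, na.strings = "NA")
}
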