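#' @include AllClasses.R io.R
NULL

#' Serialise / restore an EpochSet as a directory
#'
#' The directory holds \code{epochs.json} (dimensions, lock type, sampling
#' rate, epoch length, conditions, channel names), \code{data.bin} (the
#' epochs x channels x time tensor as little-endian doubles in
#' column-major order) and \code{log.tsv} (the candidate rejection log).
#'
#' @param epochs an [EpochSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
saveEpochSet <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(dim = dim(epochs@data), lock = epochs@lock, fs = epochs@fs,
               epoch_length_ms = epochs@epochLengthMs,
               conditions = epochs@conditions, channel_names = epochs@channelNames)
  jsonlite::write_json(meta, file.path(dir, "epochs.json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.numeric(epochs@data), con, size = 8, endian = "little")
  close(con)
  saveTable(epochs@rejectionLog, file.path(dir, "log.tsv"))
  invisible(dir)
}

#' @rdname saveEpochSet
#' @return \code{loadEpochSet}: the restored [EpochSet-class].
#' @export
loadEpochSet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "epochs.json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  x <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  close(con)
  log <- readTableTsv(file.path(dir, "log.tsv"))
  log$reason <- as.character(log$reason)
  log$reason[is.na(log$reason) & log$accepted] <- NA_character_
  new("EpochSet", data = array(x, meta$dim), lock = meta$lock, fs = meta$fs,
      epochLengthMs = meta$epoch_length_ms,
      conditions = as.character(meta$conditions),
      channelNames = as.character(meta$channel_names), rejectionLog = log)
}
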