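#' @import methods
NULL

GROUP_LEVELS <- c("MCS", "UWS", "CONTROL", "UNKNOWN")
CONDITION_LEVELS <- c("LSGS", "LSGD", "LDGS", "LDGD")
BLOCK_LEVELS <- c("XX", "XY")
LOCK_LEVELS <- c("STIMULUS_5TH", "RPEAK_POST_5TH", "RPEAK_ALL")
HB_SOURCES <- c("TRUE", "DETECTED", "SURROGATE")
REJECT_REASONS <- c("STIM20MS", "IBI500", "ECTOPIC", "AMP300", "EDGE")

#' Sensor layout: channel names and 3-D positions
#'
#' Holds the montage geometry used for neighbourhood definitions and
#' spherical-spline interpolation. Positions are Cartesian coordinates in cm
#' (typically on a head-sized cap).
#'
#' @slot names character vector of unique channel labels.
#' @slot positions numeric matrix, one row per channel, columns x/y/z in cm.
#' @exportClass SensorLayout
setClass("SensorLayout",
  representation(names = "character", positions = "matrix"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(object@names)) msg <- c(msg, "channel names must be unique")
    if (nrow(object@positions) != length(object@names))
      msg <- c(msg, "positions must have one row per channel")
    if (ncol(object@positions) != 3) msg <- c(msg, "positions must have 3 columns (x, y, z)")
    if (length(object@positions) && !all(is.finite(object@positions)))
      msg <- c(msg, "positions must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a SensorLayout
#' @param names character channel labels.
#' @param positions numeric matrix (n x 3) of x/y/z positions in cm.
#' @return A [SensorLayout-class] object.
#' @export
SensorLayout <- function(names, positions) {
  positions <- as.matrix(positions)
  dimnames(positions) <- list(names, c("x_cm", "y_cm", "z_cm"))
  new("SensorLayout", names = as.character(names), positions = positions)
}

#' Single-subject EEG recording
#'
#' The central raw-data container: a channels x samples matrix in microvolts,
#' its sampling rate, the sensor layout, the auditory event table of the
#' local-global paradigm, and an ordered preprocessing log.
#'
#' @slot subjectId subject identifier.
#' @slot group diagnostic group: MCS, UWS, CONTROL or UNKNOWN.
#' @slot eeg numeric matrix channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot layout [SensorLayout-class] matching the EEG rows.
#' @slot events data.frame with columns onset_sample, trial_id, sound_index,
#'   block_type, condition (0-based onset samples).
#' @slot preprocLog character vector of applied-step descriptors.
#' @exportClass Recording
setClass("Recording",
  representation(subjectId = "character", group = "character", eeg = "matrix",
                 fs = "numeric", layout = "SensorLayout", events = "data.frame",
                 preprocLog = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@group %in% GROUP_LEVELS) msg <- c(msg, "unknown group label")
    if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a positive scalar")
    if (nrow(object@eeg) != length(object@layout@names))
      msg <- c(msg, "channel count must match layout entries")
    ev <- object@events
    if (nrow(ev)) {
      need <- c("onset_sample", "trial_id", "sound_index", "block_type", "condition")
      if (!all(need %in% names(ev))) {
        msg <- c(msg, paste("events must have columns:", paste(need, collapse = ", ")))
      } else {
        if (any(ev$onset_sample < 0) || any(ev$onset_sample >= ncol(object@eeg)))
          msg <- c(msg, "event onset samples must lie within the recording")
        if (!all(ev$condition %in% CONDITION_LEVELS)) msg <- c(msg, "invalid condition labels")
        if (!all(ev$block_type %in% BLOCK_LEVELS)) msg <- c(msg, "invalid block_type labels")
        if (!all(ev$sound_index %in% 1:5)) msg <- c(msg, "sound_index must be 1..5")
        for (tid in unique(ev$trial_id)) {
          tr <- ev[ev$trial_id == tid, ]
          if (nrow(tr) != 5) { msg <- c(msg, "every trial must have exactly five sounds"); break }
          tr <- tr[order(tr$sound_index), ]
          if (any(diff(tr$onset_sample) <= 0)) { msg <- c(msg, "within-trial onsets must be strictly increasing"); break }
          if (length(unique(tr$condition)) != 1) { msg <- c(msg, "condition must be constant within a trial"); break }
        }
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Construct a Recording
#' @param eeg channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param layout [SensorLayout-class].
#' @param events auditory event data.frame (may be empty).
#' @param subjectId subject identifier.
#' @param group diagnostic group label.
#' @param preprocLog character log of applied steps.
#' @return A [Recording-class] object.
#' @export
Recording <- function(eeg, fs, layout, events = emptyEvents(), subjectId = "s01",
                      group = "UNKNOWN", preprocLog = character()) {
  eeg <- as.matrix(eeg)
  rownames(eeg) <- layout@names
  new("Recording", subjectId = subjectId, group = group, eeg = eeg, fs = fs,
      layout = layout, events = events, preprocLog = preprocLog)
}

#' Empty auditory event table
#' @return zero-row data.frame with the canonical event columns.
#' @export
emptyEvents <- function() {
  data.frame(onset_sample = integer(), trial_id = integer(), sound_index = integer(),
             block_type = character(), condition = character(), stringsAsFactors = FALSE)
}

#' Channel neighbourhood graph
#'
#' Undirected adjacency between sensors at Euclidean distance at most
#' \code{maxDistanceCm} (inclusive), used for cluster formation and
#' interpolation.
#'
#' @slot adjacency list, per channel, of integer neighbour indices.
#' @slot maxDistanceCm distance threshold in cm.
#' @slot channelNames channel labels the indices refer to.
#' @exportClass NeighborGraph
setClass("NeighborGraph",
  representation(adjacency = "list", maxDistanceCm = "numeric", channelNames = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@adjacency)
    if (n != length(object@channelNames)) msg <- c(msg, "adjacency length must match channel names")
    for (i in seq_len(n)) {
      nb <- object@adjacency[[i]]
      if (i %in% nb) { msg <- c(msg, "graph must be irreflexive"); break }
      if (!all(vapply(nb, function(j) i %in% object@adjacency[[j]], logical(1)))) {
        msg <- c(msg, "graph must be symmetric"); break
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Heartbeat series: R-peaks, interbeat intervals and ectopic flags
#'
#' @slot rpeakSamples strictly increasing integer sample indices (0-based).
#' @slot fs sampling rate of the trace the peaks refer to (Hz).
#' @slot ibiMs interbeat intervals in ms (length = peaks - 1).
#' @slot ectopicFlags logical flags aligned to \code{ibiMs}.
#' @slot source provenance: TRUE (simulated ground truth), DETECTED, SURROGATE.
#' @exportClass HeartbeatSeries
setClass("HeartbeatSeries",
  representation(rpeakSamples = "numeric", fs = "numeric", ibiMs = "numeric",
                 ectopicFlags = "logical", source = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@rpeakSamples) > 1 && any(diff(object@rpeakSamples) <= 0))
      msg <- c(msg, "R-peak samples must be strictly increasing")
    if (length(object@ibiMs) != max(0L, length(object@rpeakSamples) - 1L))
      msg <- c(msg, "ibiMs length must be number of peaks - 1")
    if (length(object@ibiMs)) {
      expect <- diff(object@rpeakSamples) * 1000 / object@fs
      if (max(abs(object@ibiMs - expect)) > 1e-6)
        msg <- c(msg, "ibiMs must equal diff(rpeakSamples) * 1000 / fs")
    }
    if (length(object@ectopicFlags) != length(object@ibiMs))
      msg <- c(msg, "ectopicFlags length must equal ibiMs length")
    if (!object@source %in% HB_SOURCES) msg <- c(msg, "invalid source")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a HeartbeatSeries from peak samples
#' @param rpeakSamples strictly increasing 0-based sample indices.
#' @param fs sampling rate (Hz).
#' @param source one of "TRUE", "DETECTED", "SURROGATE".
#' @param ectopicFlags optional logical flags per interbeat interval.
#' @return A [HeartbeatSeries-class].
#' @export
HeartbeatSeries <- function(rpeakSamples, fs, source = "DETECTED", ectopicFlags = NULL) {
  rpeakSamples <- as.numeric(rpeakSamples)
  ibi <- if (length(rpeakSamples) > 1) diff(rpeakSamples) * 1000 / fs else numeric()
  if (is.null(ectopicFlags)) ectopicFlags <- rep(FALSE, length(ibi))
  new("HeartbeatSeries", rpeakSamples = rpeakSamples, fs = fs, ibiMs = ibi,
      ectopicFlags = ectopicFlags, source = source)
}

#' Epoch set locked to stimuli or R-peaks
#'
#' @slot data numeric array epochs x channels x time (microvolts).
#' @slot lock one of STIMULUS_5TH, RPEAK_POST_5TH, RPEAK_ALL.
#' @slot fs sampling rate (Hz).
#' @slot epochLengthMs epoch length in ms (half-open window from the lock).
#' @slot conditions per-epoch condition labels ("NONE" for RPEAK_ALL).
#' @slot channelNames channel labels for the second dimension.
#' @slot rejectionLog data.frame: candidate, lock_sample, accepted, reason.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(data = "array", lock = "character", fs = "numeric",
                 epochLengthMs = "numeric", conditions = "character",
                 channelNames = "character", rejectionLog = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!object@lock %in% LOCK_LEVELS) msg <- c(msg, "invalid lock type")
    if (length(dim(object@data)) != 3) msg <- c(msg, "data must be epochs x channels x time")
    else {
      if (dim(object@data)[1] != length(object@conditions))
        msg <- c(msg, "conditions length must match epoch count")
      if (dim(object@data)[2] != length(object@channelNames))
        msg <- c(msg, "channelNames must match channel dimension")
      if (length(object@data) && !all(is.finite(object@data))) msg <- c(msg, "data must be finite")
    }
    rl <- object@rejectionLog
    if (nrow(rl)) {
      bad <- !rl$accepted & !rl$reason %in% REJECT_REASONS
      if (any(bad)) msg <- c(msg, "rejected candidates must carry a known reason code")
      if (sum(rl$accepted) != dim(object@data)[1])
        msg <- c(msg, "epoch count must equal accepted candidates")
    }
    if (length(msg)) msg else TRUE
  }
)

#' Subject-level contrast map (deviant minus standard)
#'
#' @slot subjectId subject identifier.
#' @slot signal "ERP" or "HER".
#' @slot level "LOCAL" or "GLOBAL".
#' @slot map channels x time numeric matrix (microvolts).
#' @slot nDeviant,nStandard epoch counts entering each side of the contrast.
#' @slot fs sampling rate (Hz).
#' @slot channelNames channel labels for the rows of \code{map}.
#' @exportClass EffectMap
setClass("EffectMap",
  representation(subjectId = "character", signal = "character", level = "character",
                 map = "matrix", nDeviant = "numeric", nStandard = "numeric",
                 fs = "numeric", channelNames = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@signal %in% c("ERP", "HER")) msg <- c(msg, "signal must be ERP or HER")
    if (!object@level %in% c("LOCAL", "GLOBAL")) msg <- c(msg, "level must be LOCAL or GLOBAL")
    if (nrow(object@map) != length(object@channelNames))
      msg <- c(msg, "map rows must match channelNames")
    if (object@nDeviant <= 0 || object@nStandard <= 0)
      msg <- c(msg, "both contrast sides need at least one epoch")
    if (length(msg)) msg else TRUE
  }
)

#' Result of the spatiotemporal cluster-permutation test
#'
#' @slot z channels x time matrix of unpaired Wilcoxon rank-sum Z values
#'   (orientation group A minus group B).
#' @slot p pointwise two-sided p values (normal approximation).
#' @slot clusters list of cluster descriptors (members, sign, nChannels, size,
#'   stat, latencyMs, mcP).
#' @slot permDistribution per-partition max-|Z| statistics.
#' @slot nPartitions number of partitions used.
#' @slot exhaustive TRUE when all distinct partitions were enumerated.
#' @slot seed RNG seed used for the random partitions.
#' @slot combinedEffects data.frame of per-subject combined clustered effects.
#' @slot fs sampling rate of the time axis (Hz).
#' @slot channelNames channel labels.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(z = "matrix", p = "matrix", clusters = "list",
                 permDistribution = "numeric", nPartitions = "numeric",
                 exhaustive = "logical", seed = "numeric",
                 combinedEffects = "data.frame", fs = "numeric",
                 channelNames = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@permDistribution) != object@nPartitions)
      msg <- c(msg, "permutation distribution length must equal nPartitions")
    for (cl in object@clusters) {
      if (!is.null(cl$mcP) && (cl$mcP < 0 || cl$mcP > 1)) { msg <- c(msg, "mcP must lie in [0, 1]"); break }
    }
    if (length(msg)) msg else TRUE
  }
)
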