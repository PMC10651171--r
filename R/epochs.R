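#' @include AllClasses.R utils.R
NULL

# assemble accepted epochs into an epochs x channels x time array
buildEpochArray <- function(eeg, locks, L) {
  nCh <- nrow(eeg)
  arr <- array(0, dim = c(length(locks), nCh, L))
  for (k in seq_along(locks)) {
    idx <- locks[k] + seq_len(L)     # 0-based lock -> 1-based columns, [lock, lock+L)
    arr[k, , ] <- eeg[, idx]
  }
  arr
}

#' Stimulus-locked (ERP) epoching with amplitude rejection
#'
#' One candidate epoch per trial, locked at the 5th-sound onset, spanning
#' \code{[0, epochLengthMs)}. Candidates with absolute amplitude above
#' \code{ampRejectUv} on any channel are rejected (AMP300); epochs that would
#' overrun the recording are rejected (EDGE).
#'
#' @param recording a preprocessed [Recording-class] with events.
#' @param ampRejectUv amplitude threshold in microvolts (default 300).
#' @param epochLengthMs epoch length (default 1000 ms).
#' @return An [EpochSet-class] with lock "STIMULUS_5TH".
#' @export
epochStimulus <- function(recording, ampRejectUv = 300, epochLengthMs = 1000) {
  ev <- recording@events
  if (!nrow(ev)) stop("epochStimulus: recording has no events")
  fifth <- ev[ev$sound_index == 5, ]
  L <- round(epochLengthMs * recording@fs / 1000)
  n <- ncol(recording@eeg)
  locks <- fifth$onset_sample
  reason <- rep(NA_character_, nrow(fifth))
  for (k in seq_len(nrow(fifth))) {
    lo <- locks[k]; hi <- locks[k] + L - 1
    avail <- min(hi, n - 1)
    seg <- recording@eeg[, (lo + 1):(avail + 1), drop = FALSE]
    if (max(abs(seg)) > ampRejectUv) reason[k] <- "AMP300"
    else if (hi >= n) reason[k] <- "EDGE"
  }
  acc <- is.na(reason)
  if (!any(acc)) stop("epochStimulus: zero surviving epochs (degenerate output)")
  log <- data.frame(candidate = seq_len(nrow(fifth)), lock_sample = locks,
                    accepted = acc, reason = reason, stringsAsFactors = FALSE)
  new("EpochSet", data = buildEpochArray(recording@eeg, locks[acc], L),
      lock = "STIMULUS_5TH", fs = recording@fs, epochLengthMs = epochLengthMs,
      conditions = fifth$condition[acc], channelNames = recording@layout@names,
      rejectionLog = log)
}

#' Heartbeat-locked epoching on the beats following each 5th sound
#'
#' The lock point of a trial is the first R-peak strictly after its 5th-sound
#' onset; the epoch spans \code{[0, epochLengthMs)} from that peak and
#' inherits the trial's condition. Rejection reasons are evaluated in the
#' fixed order STIM20MS (5th sound closer than the guard to its nearest
#' R-peak, either direction), IBI500 (the lock peak's preceding or following
#' interval shorter than the floor), ECTOPIC (the lock peak bounds a flagged
#' interval), AMP300, EDGE; each rejected candidate carries the first
#' matching code.
#'
#' @param recording a preprocessed [Recording-class] with events.
#' @param hb a [HeartbeatSeries-class] (ectopic flags honoured).
#' @param ampRejectUv amplitude threshold (default 300 microvolts).
#' @param ibiFloorMs minimum adjacent interbeat interval (default 500 ms).
#' @param stimGuardMs stimulus-to-peak guard (default 20 ms).
#' @param epochLengthMs epoch length (default 500 ms).
#' @param guardAllSounds apply the guard to all five sounds of the trial
#'   rather than the 5th only (default FALSE).
#' @return An [EpochSet-class] with lock "RPEAK_POST_5TH".
#' @export
epochHeartbeatPostStimulus <- function(recording, hb, ampRejectUv = 300,
                                       ibiFloorMs = 500, stimGuardMs = 20,
                                       epochLengthMs = 500, guardAllSounds = FALSE) {
  ev <- recording@events
  if (!nrow(ev)) stop("epochHeartbeatPostStimulus: recording has no events")
  if (!length(hb@rpeakSamples)) stop("epochHeartbeatPostStimulus: no heartbeats")
  fs <- recording@fs
  fifth <- ev[ev$sound_index == 5, ]
  L <- round(epochLengthMs * fs / 1000)
  n <- ncol(recording@eeg)
  peaks <- hb@rpeakSamples
  nearestPeakMs <- function(onset) {
    min(abs(onset - peaks)) * 1000 / fs
  }
  locks <- rep(NA_real_, nrow(fifth))
  reason <- rep(NA_character_, nrow(fifth))
  for (k in seq_len(nrow(fifth))) {
    on5 <- fifth$onset_sample[k]
    guardOnsets <- if (guardAllSounds) ev$onset_sample[ev$trial_id == fifth$trial_id[k]] else on5
    j <- findInterval(on5, peaks) + 1L    # first peak strictly after (peaks 0-based)
    while (j <= length(peaks) && peaks[j] <= on5) j <- j + 1L
    if (any(vapply(guardOnsets, nearestPeakMs, 0) < stimGuardMs)) {
      reason[k] <- "STIM20MS"; next
    }
    if (j > length(peaks)) { reason[k] <- "EDGE"; next }
    locks[k] <- peaks[j]
    prevIbi <- if (j > 1) hb@ibiMs[j - 1] else Inf
    nextIbi <- if (j <= length(hb@ibiMs)) hb@ibiMs[j] else Inf
    if (prevIbi < ibiFloorMs || nextIbi < ibiFloorMs) { reason[k] <- "IBI500"; next }
    prevFlag <- if (j > 1) hb@ectopicFlags[j - 1] else FALSE
    nextFlag <- if (j <= length(hb@ectopicFlags)) hb@ectopicFlags[j] else FALSE
    if (isTRUE(prevFlag) || isTRUE(nextFlag)) { reason[k] <- "ECTOPIC"; next }
    lo <- locks[k]; hi <- lo + L - 1
    avail <- min(hi, n - 1)
    seg <- recording@eeg[, (lo + 1):(avail + 1), drop = FALSE]
    if (max(abs(seg)) > ampRejectUv) { reason[k] <- "AMP300"; next }
    if (hi >= n) { reason[k] <- "EDGE"; next }
  }
  acc <- is.na(reason)
  if (!any(acc)) stop("epochHeartbeatPostStimulus: zero surviving epochs (degenerate output)")
  log <- data.frame(candidate = seq_len(nrow(fifth)), lock_sample = locks,
                    accepted = acc, reason = reason, stringsAsFactors = FALSE)
  new("EpochSet", data = buildEpochArray(recording@eeg, locks[acc], L),
      lock = "RPEAK_POST_5TH", fs = fs, epochLengthMs = epochLengthMs,
      conditions = fifth$condition[acc], channelNames = recording@layout@names,
      rejectionLog = log)
}

#' Heartbeat-locked epoching over all beats of the protocol
#'
#' One candidate per R-peak, independent of the stimuli (conditions "NONE"),
#' with the same IBI500 / ECTOPIC / AMP300 / EDGE rules and no stimulus guard.
#'
#' @inheritParams epochHeartbeatPostStimulus
#' @return An [EpochSet-class] with lock "RPEAK_ALL".
#' @export
epochAllHeartbeats <- function(recording, hb, ampRejectUv = 300, ibiFloorMs = 500,
                               epochLengthMs = 500) {
  if (!length(hb@rpeakSamples)) stop("epochAllHeartbeats: no heartbeats")
  fs <- recording@fs
  L <- round(epochLengthMs * fs / 1000)
  n <- ncol(recording@eeg)
  peaks <- hb@rpeakSamples
  reason <- rep(NA_character_, length(peaks))
  for (j in seq_along(peaks)) {
    prevIbi <- if (j > 1) hb@ibiMs[j - 1] else Inf
    nextIbi <- if (j <= length(hb@ibiMs)) hb@ibiMs[j] else Inf
    if (prevIbi < ibiFloorMs || nextIbi < ibiFloorMs) { reason[j] <- "IBI500"; next }
    prevFlag <- if (j > 1) hb@ectopicFlags[j - 1] else FALSE
    nextFlag <- if (j <= length(hb@ectopicFlags)) hb@ectopicFlags[j] else FALSE
    if (isTRUE(prevFlag) || isTRUE(nextFlag)) { reason[j] <- "ECTOPIC"; next }
    lo <- peaks[j]; hi <- lo + L - 1
    avail <- min(hi, n - 1)
    seg <- recording@eeg[, (lo + 1):(avail + 1), drop = FALSE]
    if (max(abs(seg)) > ampRejectUv) { reason[j] <- "AMP300"; next }
    if (hi >= n) { reason[j] <- "EDGE"; next }
  }
  acc <- is.na(reason)
  if (!any(acc)) stop("epochAllHeartbeats: zero surviving epochs (degenerate output)")
  log <- data.frame(candidate = seq_along(peaks), lock_sample = peaks,
                    accepted = acc, reason = reason, stringsAsFactors = FALSE)
  new("EpochSet", data = buildEpochArray(recording@eeg, peaks[acc], L),
      lock = "RPEAK_ALL", fs = fs, epochLengthMs = epochLengthMs,
      conditions = rep("NONE", sum(acc)), channelNames = recording@layout@names,
      rejectionLog = log)
}

conditionSides <- function(level) {
  if (level == "LOCAL") list(deviant = c("LDGS", "LDGD"), standard = c("LSGS", "LSGD"))
  else list(deviant = c("LSGD", "LDGD"), standard = c("LSGS", "LDGS"))
}

#' Subject-level local or global contrast map
#'
#' LOCAL: pooled mean over local-deviant epochs (LDGS + LDGD) minus pooled
#' mean over local-standard epochs (LSGS + LSGD). GLOBAL: pooled mean over
#' global deviants (LSGD + LDGD) minus global standards (LSGS + LDGS).
#' Pooling is over epochs (trial-count weighted); \code{pooling = "means"}
#' averages the two condition means on each side instead.
#'
#' @param epochs a condition-labelled [EpochSet-class].
#' @param level "LOCAL" or "GLOBAL".
#' @param signal "ERP" or "HER" tag for the resulting map (defaults from the
#'   epoch lock type).
#' @param subjectId identifier carried into the map.
#' @param pooling "epochs" (default) or "means".
#' @return An [EffectMap-class] (channels x time, microvolts).
#' @export
subjectEffect <- function(epochs, level = c("LOCAL", "GLOBAL"),
                          signal = if (epochs@lock == "STIMULUS_5TH") "ERP" else "HER",
                          subjectId = "s01", pooling = c("epochs", "means")) {
  level <- match.arg(level)
  pooling <- match.arg(pooling)
  sides <- conditionSides(level)
  cond <- epochs@conditions
  iDev <- which(cond %in% sides$deviant)
  iStd <- which(cond %in% sides$standard)
  if (!length(iDev) || !length(iStd)) {
    missing <- c(if (!length(iDev)) sides$deviant, if (!length(iStd)) sides$standard)
    stop("subjectEffect: empty contrast side; missing conditions: ",
         paste(missing, collapse = ", "))
  }
  epochMean <- function(idx) {
    d <- dim(epochs@data)
    matrix(colMeans(epochs@data[idx, , , drop = FALSE]), d[2], d[3])
  }
  meanOver <- function(idx) {
    if (pooling == "epochs") {
      epochMean(idx)
    } else {
      present <- unique(cond[idx])
      ms <- lapply(present, function(cc) epochMean(idx[cond[idx] == cc]))
      Reduce(`+`, ms) / length(ms)
    }
  }
  map <- meanOver(iDev) - meanOver(iStd)
  new("EffectMap", subjectId = subjectId, signal = signal, level = level,
      map = map, nDeviant = length(iDev), nStandard = length(iStd),
      fs = epochs@fs, channelNames = epochs@channelNames)
}

#' Whole-protocol HER mean and variance maps
#'
#' Per channel x time sample, the mean and unbiased (n - 1) variance across
#' all accepted heartbeat-locked epochs, independent of stimuli.
#'
#' @param epochs an [EpochSet-class] (typically lock "RPEAK_ALL", >= 2 epochs).
#' @return list with \code{mean} and \code{variance} channels x time matrices.
#' @export
herSummaryWholeProtocol <- function(epochs) {
  d <- dim(epochs@data)
  if (d[1] < 2) stop("herSummaryWholeProtocol: need at least 2 epochs")
  m <- colMeans(epochs@data)
  s2 <- colMeans(epochs@data^2)
  list(mean = matrix(m, d[2], d[3]),
       variance = matrix((s2 - m^2) * d[1] / (d[1] - 1), d[2], d[3]))
}

#' Per-trial 5th-sound to lock-R-peak latencies
#'
#' @param recording a [Recording-class] with events.
#' @param hb a [HeartbeatSeries-class].
#' @return data.frame trial_id, condition, latency_ms (NA when no following
#'   peak exists).
#' @export
lockLatencies <- function(recording, hb) {
  fifth <- recording@events[recording@events$sound_index == 5, ]
  peaks <- hb@rpeakSamples
  lat <- vapply(fifth$onset_sample, function(on5) {
    j <- findInterval(on5, peaks) + 1L
    while (j <= length(peaks) && peaks[j] <= on5) j <- j + 1L
    if (j > length(peaks)) NA_real_ else (peaks[j] - on5) * 1000 / recording@fs
  }, 0)
  data.frame(trial_id = fifth$trial_id, condition = fifth$condition,
             latency_ms = lat, stringsAsFactors = FALSE)
}

LATENCY_CATEGORIES <- list(
  local_standard = c("LSGS", "LSGD"), local_deviant = c("LDGS", "LDGD"),
  global_standard = c("LSGS", "LDGS"), global_deviant = c("LSGD", "LDGD")
)

#' Latency-balance control test between groups
#'
#' Unpaired Wilcoxon rank-sum tests, per pooled condition category (local
#' standard/deviant, global standard/deviant), on the per-subject mean
#' 5th-sound-to-lock-R-peak latencies, checking that heartbeat-locking
#' latencies do not differ between the two groups.
#'
#' @param latencies data.frame with columns subject, group, condition (one of
#'   local_standard, local_deviant, global_standard, global_deviant) and
#'   latency_ms (one row per subject x category).
#' @param groupA,groupB the two group labels to compare (default MCS vs UWS).
#' @return data.frame condition, Z, p, nA, nB.
#' @export
latencyBalanceTest <- function(latencies, groupA = "MCS", groupB = "UWS") {
  conds <- names(LATENCY_CATEGORIES)
  out <- lapply(conds, function(cc) {
    d <- latencies[latencies$condition == cc, ]
    a <- d$latency_ms[d$group == groupA]
    b <- d$latency_ms[d$group == groupB]
    if (length(a) < 2 || length(b) < 2)
      stop("latencyBalanceTest: need at least 2 subjects per group (", cc, ")")
    r <- rankSumZ(a, b)
    data.frame(condition = cc, Z = r$Z, p = r$p, nA = length(a), nB = length(b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-subject mean lock latencies by pooled condition category
#'
#' Convenience aggregation feeding [latencyBalanceTest()].
#'
#' @param recording a [Recording-class].
#' @param hb a [HeartbeatSeries-class].
#' @param subject subject identifier for the output rows.
#' @param group group label for the output rows.
#' @return data.frame subject, group, condition, latency_ms.
#' @export
subjectMeanLatencies <- function(recording, hb, subject = recording@subjectId,
                                 group = recording@group) {
  ll <- lockLatencies(recording, hb)
  rows <- lapply(names(LATENCY_CATEGORIES), function(cc) {
    v <- ll$latency_ms[ll$condition %in% LATENCY_CATEGORIES[[cc]]]
    data.frame(subject = subject, group = group, condition = cc,
               latency_ms = mean(v, na.rm = TRUE), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
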