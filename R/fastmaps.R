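#' @include AllClasses.R utils.R epochs.R
NULL

# Vectorised contrast-map computation sharing the exact rejection rules of
# the EpochSet path but skipping epoch materialisation; used by the heavy
# resampling studies (surrogates, planted recovery) where thousands of
# re-epochings occur. Equality with the EpochSet path is asserted in tests.

# accepted HER lock samples + conditions for a recording/heartbeat pair
herAcceptedLocks <- function(recording, hb, ampRejectUv, ibiFloorMs, stimGuardMs, L) {
  fifth <- recording@events[recording@events$sound_index == 5, ]
  o <- fifth$onset_sample
  p <- hb@rpeakSamples
  np <- length(p)
  fs <- recording@fs
  n <- ncol(recording@eeg)
  jPrev <- findInterval(o, p)                  # last peak <= onset (0 if none)
  j <- jPrev + 1L                              # first peak strictly after
  dupAtOnset <- jPrev >= 1 & p[pmax(jPrev, 1)] == o
  # nearest peak distance (either direction), ms
  dPrev <- ifelse(jPrev >= 1, o - p[pmax(jPrev, 1)], Inf)
  dNext <- ifelse(j <= np, p[pmin(j, np)] - o, Inf)
  nearestMs <- pmin(dPrev, dNext) * 1000 / fs
  hasLock <- j <= np
  lock <- ifelse(hasLock, p[pmin(j, np)], NA_real_)
  prevIbi <- ifelse(j > 1 & hasLock, hb@ibiMs[pmax(j - 1, 1)], Inf)
  nextIbi <- ifelse(hasLock & j <= length(hb@ibiMs), hb@ibiMs[pmin(j, max(length(hb@ibiMs), 1))], Inf)
  fl <- hb@ectopicFlags
  prevFlag <- ifelse(j > 1 & hasLock & length(fl) > 0, fl[pmax(j - 1, 1)], FALSE)
  nextFlag <- ifelse(hasLock & j <= length(fl), fl[pmin(j, max(length(fl), 1))], FALSE)
  ok <- nearestMs >= stimGuardMs & hasLock &
    prevIbi >= ibiFloorMs & nextIbi >= ibiFloorMs &
    !prevFlag & !nextFlag & !is.na(lock) & (lock + L - 1 < n)
  list(locks = lock[ok], conditions = fifth$condition[ok])
}

# extract epochs at `locks`, drop amplitude-violating ones, return the
# channels x time condition means and counts
lockedConditionMeans <- function(eeg, locks, conditions, L, ampRejectUv) {
  nCh <- nrow(eeg)
  if (!length(locks)) return(NULL)
  idx <- as.vector(t(outer(locks, 0:(L - 1), `+`))) + 1L
  E <- eeg[, idx, drop = FALSE]
  B <- array(E, c(nCh, L, length(locks)))
  amp <- apply(abs(B), 3, max)
  keep <- amp <= ampRejectUv
  B <- B[, , keep, drop = FALSE]
  conditions <- conditions[keep]
  conds <- unique(conditions)
  means <- lapply(conds, function(cc)
    rowMeans(B[, , conditions == cc, drop = FALSE], dims = 2))
  names(means) <- conds
  list(means = means, counts = table(factor(conditions, conds)))
}

pooledContrast <- function(cm, level) {
  sides <- conditionSides(level)
  pool <- function(set) {
    set <- intersect(set, names(cm$means))
    if (!length(set)) return(NULL)
    w <- as.numeric(cm$counts[set])
    Reduce(`+`, Map(`*`, cm$means[set], w)) / sum(w)
  }
  dev <- pool(sides$deviant); std <- pool(sides$standard)
  if (is.null(dev) || is.null(std)) return(NULL)
  dev - std
}

# fast HER LOCAL/GLOBAL maps; NULL when a contrast side is empty
fastHerMaps <- function(recording, hb, ampRejectUv = 300, ibiFloorMs = 500,
                        stimGuardMs = 20, epochLengthMs = 500) {
  L <- round(epochLengthMs * recording@fs / 1000)
  al <- herAcceptedLocks(recording, hb, ampRejectUv, ibiFloorMs, stimGuardMs, L)
  cm <- lockedConditionMeans(recording@eeg, al$locks, al$conditions, L, ampRejectUv)
  if (is.null(cm)) return(NULL)
  list(LOCAL = pooledContrast(cm, "LOCAL"), GLOBAL = pooledContrast(cm, "GLOBAL"))
}

# fast ERP LOCAL/GLOBAL maps (stimulus-locked; AMP + EDGE rules only)
fastErpMaps <- function(recording, ampRejectUv = 300, epochLengthMs = 1000) {
  fs <- recording@fs
  L <- round(epochLengthMs * fs / 1000)
  fifth <- recording@events[recording@events$sound_index == 5, ]
  ok <- fifth$onset_sample + L - 1 < ncol(recording@eeg)
  cm <- lockedConditionMeans(recording@eeg, fifth$onset_sample[ok],
                             fifth$condition[ok], L, ampRejectUv)
  if (is.null(cm)) return(NULL)
  list(LOCAL = pooledContrast(cm, "LOCAL"), GLOBAL = pooledContrast(cm, "GLOBAL"))
}
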