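#' @include AllClasses.R utils.R
NULL

# core single-orientation detector: window-maximum local peaks above an
# adaptive amplitude floor, thinned by a refractory period
detectCore <- function(x, fs, windowMs, refractoryMs, floorFrac) {
  n <- length(x)
  h <- max(1L, floor(round(windowMs * fs / 1000) / 2))
  refr <- round(refractoryMs * fs / 1000)
  cand <- which(diff(sign(diff(x))) < 0) + 1L          # strict-ish local maxima
  cand <- cand[x[cand] > x[cand + 1L] & x[cand] >= x[cand - 1L]]
  if (!length(cand)) return(integer(0))
  isWinMax <- vapply(cand, function(i)
    x[i] >= max(x[max(1L, i - h):min(n, i + h)]), logical(1))
  strong <- cand[isWinMax]
  if (!length(strong)) return(integer(0))
  floorAmp <- floorFrac * as.numeric(quantile(x[strong], 0.95))
  strong <- strong[x[strong] > floorAmp]
  if (length(strong) < 2) return(strong)
  ord <- strong[order(x[strong], decreasing = TRUE)]
  accepted <- integer(0)
  for (p in ord) {
    if (!length(accepted) || min(abs(accepted - p)) >= refr) accepted <- c(accepted, p)
  }
  sort(accepted)
}

#' Detect R-peaks on an ECG-like trace
#'
#' Sliding-window local-maximum detector: peaks are local maxima that are the
#' maximum within their window and exceed an adaptive amplitude floor
#' (\code{floorFrac} of the 95th percentile of window-maximum amplitudes); no
#' two peaks lie closer than the refractory period. Polarity is resolved
#' automatically: detection runs on both the trace and its negation and the
#' orientation with the larger median peak amplitude wins, so an inverted
#' ECG yields identical peak samples.
#'
#' @param ecg numeric trace.
#' @param fs sampling rate (Hz).
#' @param windowMs sliding-window length (default 600 ms).
#' @param refractoryMs minimum peak separation (default 300 ms).
#' @param floorFrac adaptive amplitude floor fraction (default 0.4).
#' @return A [HeartbeatSeries-class] with source "DETECTED" (empty, with a
#'   warning, when nothing is found).
#' @export
detectRPeaks <- function(ecg, fs, windowMs = 600, refractoryMs = 300, floorFrac = 0.4) {
  if (length(ecg) <= round(windowMs * fs / 1000))
    stop("detectRPeaks: trace shorter than the detection window")
  up <- detectCore(ecg, fs, windowMs, refractoryMs, floorFrac)
  dn <- detectCore(-ecg, fs, windowMs, refractoryMs, floorFrac)
  scoreUp <- if (length(up)) median(ecg[up]) else -Inf
  scoreDn <- if (length(dn)) median(-ecg[dn]) else -Inf
  peaks <- if (scoreDn > scoreUp) dn else up
  if (!length(peaks)) {
    warning("detectRPeaks: no peaks found")
    return(HeartbeatSeries(numeric(0), fs, source = "DETECTED"))
  }
  HeartbeatSeries(peaks - 1, fs, source = "DETECTED")   # 0-based samples
}

#' Flag ectopic interbeat intervals
#'
#' Computes the first difference of the interbeat-interval series and flags
#' the two intervals adjacent to each suprathreshold peak of its absolute
#' value (a peak is a local maximum of |diff| exceeding the threshold). The
#' default threshold is \code{derivThreshold} robust SDs, with the robust
#' scale taken as the MAD of the interval series. Flagged intervals are kept
#' in the record but excluded as heartbeat-locked epoch lock points.
#'
#' @param series a [HeartbeatSeries-class] with at least 3 intervals.
#' @param derivThreshold threshold in robust-SD units (default 3); may be Inf.
#' @return the series with updated \code{ectopicFlags}.
#' @export
flagEctopic <- function(series, derivThreshold = 3) {
  ibis <- series@ibiMs
  if (length(ibis) < 3) stop("flagEctopic: need at least 3 interbeat intervals")
  d <- diff(ibis)
  thr <- derivThreshold * stats::mad(ibis)
  ad <- abs(d)
  isPeak <- vapply(seq_along(d), function(i) {
    left <- if (i > 1) ad[i - 1] else -Inf
    right <- if (i < length(d)) ad[i + 1] else -Inf
    ad[i] > thr && ad[i] >= left && ad[i] >= right
  }, logical(1))
  flags <- rep(FALSE, length(ibis))
  for (i in which(isPeak)) flags[c(i, i + 1)] <- TRUE
  out <- series
  out@ectopicFlags <- flags
  out
}

#' Apply a deterministic manual-corrections table to a heartbeat series
#'
#' Replaces interactive peak review: a corrections data.frame with columns
#' \code{action} ("add" or "remove") and \code{sample} (0-based) is applied
#' in order; intervals are recomputed.
#'
#' @param series a [HeartbeatSeries-class].
#' @param corrections data.frame(action, sample).
#' @return corrected [HeartbeatSeries-class].
#' @export
applyPeakCorrections <- function(series, corrections) {
  peaks <- series@rpeakSamples
  for (k in seq_len(nrow(corrections))) {
    a <- corrections$action[k]; s <- corrections$sample[k]
    if (a == "add") peaks <- sort(unique(c(peaks, s)))
    else if (a == "remove") peaks <- peaks[peaks != s]
    else stop("applyPeakCorrections: unknown action ", a)
  }
  HeartbeatSeries(peaks, series@fs, source = series@source)
}
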