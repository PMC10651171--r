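#' @include AllClasses.R utils.R neighbors.R
NULL

appendLog <- function(recording, step) {
  recording@preprocLog <- c(recording@preprocLog, step)
  recording
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, order 4, applied per
#' channel; removes DC and attenuates activity outside the passband. An
#' alternative Hamming-windowed FIR design is available via \code{mode}.
#'
#' @param recording a [Recording-class].
#' @param lowHz,highHz band edges in Hz (defaults 1 and 25).
#' @param order Butterworth order (default 4).
#' @param mode "iir" (Butterworth, default) or "fir" (Hamming-windowed).
#' @return filtered [Recording-class].
#' @export
bandpassFilter <- function(recording, lowHz = 1, highHz = 25, order = 4, mode = "iir") {
  fs <- recording@fs
  if (highHz >= fs / 2) stop("bandpassFilter: upper edge must be below Nyquist")
  if (fs <= 2 * highHz) stop("bandpassFilter: sampling rate too low for the requested band")
  if (mode == "iir") {
    flt <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  } else {
    n <- 2 * floor(1.65 * fs / lowHz) + 1   # odd length, ~3.3/transition-width rule
    flt <- signal::fir1(n - 1, c(lowHz, highHz) / (fs / 2), type = "pass",
                        window = signal::hamming(n))
    flt <- signal::Ma(flt)
  }
  # reflect-pad both ends so filter transients fall outside the retained data
  pad <- min(ncol(recording@eeg) - 1, 3 * round(fs))
  eeg <- t(apply(recording@eeg, 1, function(x) {
    n <- length(x)
    xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
    as.numeric(signal::filtfilt(flt, xp))[(pad + 1):(pad + n)]
  }))
  rownames(eeg) <- rownames(recording@eeg)
  recording@eeg <- eeg
  appendLog(recording, sprintf("bandpass[%g-%g Hz,%s]", lowHz, highHz, mode))
}

#' Iterative noisy-channel rejection by z-scored signal area
#'
#' Computes per channel the trapezoidal area under the absolute signal,
#' z-scores the areas across channels, removes channels above the threshold,
#' and repeats on the remaining set until no channel exceeds it (or the
#' iteration cap is hit, with a warning). Zero variance across channels means
#' nothing is rejected.
#'
#' @param recording a [Recording-class] (>= 3 channels).
#' @param zThreshold rejection threshold in SD units (default 3).
#' @param maxIter iteration cap (default 10).
#' @return list with \code{recording} (channels removed) and \code{report}
#'   (rejected channel names in removal order, per-iteration tallies).
#' @export
rejectChannelsZscore <- function(recording, zThreshold = 3, maxIter = 10) {
  if (nrow(recording@eeg) < 3) stop("rejectChannelsZscore: need at least 3 channels")
  dt <- 1 / recording@fs
  keep <- seq_len(nrow(recording@eeg))
  auc <- apply(recording@eeg, 1, function(x) trapz(abs(x), dt))
  rejected <- character()
  iters <- 0
  repeat {
    iters <- iters + 1
    a <- auc[keep]
    s <- sd(a)
    if (!is.finite(s) || s == 0) break
    z <- (a - mean(a)) / s
    bad <- which(z > zThreshold)
    if (!length(bad)) break
    if (length(keep) - length(bad) < 1)
      stop("rejectChannelsZscore: all channels rejected (degenerate input)")
    rejected <- c(rejected, recording@layout@names[keep[bad]])
    keep <- keep[-bad]
    if (iters >= maxIter) { warning("rejectChannelsZscore: iteration cap reached"); break }
  }
  out <- recording
  out@eeg <- recording@eeg[keep, , drop = FALSE]
  out@layout <- SensorLayout(recording@layout@names[keep],
                             recording@layout@positions[keep, , drop = FALSE])
  out <- appendLog(out, sprintf("reject_z[%d removed]", length(rejected)))
  list(recording = out,
       report = list(rejected_channels_zscore = rejected, n_iterations = iters,
                     z_threshold = zThreshold))
}

# symmetric FastICA (logcosh contrast) on a channels x samples matrix; the
# unmixing matrix is estimated on an evenly spaced time-subsample (the
# contrast expectations stabilise long before the full record is used) and
# applied to the full data
fastIcaDecomp <- function(X, nComp = nrow(X), seed = 1, maxIter = 200, tol = 1e-6,
                          maxEstPoints = 10000) {
  nch <- nrow(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)[seq_len(min(nComp, sum(eg$values > 0)))]
  K <- diag(1 / sqrt(eg$values[keep]), length(keep)) %*% t(eg$vectors[, keep, drop = FALSE])
  Zfull <- K %*% Xc
  Z <- if (ncol(Zfull) > maxEstPoints) {
    Zfull[, round(seq(1, ncol(Zfull), length.out = maxEstPoints)), drop = FALSE]
  } else Zfull
  m <- nrow(Z)
  W <- withSeed(seed, matrix(rnorm(m * m), m, m))
  sym <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-12)), m) %*% t(s$vectors) %*% W
  }
  W <- sym(W)
  for (it in seq_len(maxIter)) {
    U <- W %*% Z
    G <- tanh(U)
    Gp <- rowMeans(1 - G^2)
    Wn <- G %*% t(Z) / ncol(Z) - Gp * W
    Wn <- sym(Wn)
    delta <- max(abs(1 - abs(rowSums(Wn * W))))
    W <- Wn
    if (delta < tol) break
  }
  S <- W %*% Zfull
  A <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(eg$values[keep]), m) %*% t(W)
  list(S = S, A = A, W = W, K = K, mean = mu, converged = delta < tol, iterations = it)
}

excessKurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2 - 3
}

# cardiac-likeness scores: share of the power-envelope autocorrelation energy
# in the 0.6-1.5 s (heart-period) lag band, and excess kurtosis of the
# component (QRS trains are sparse spikes); the envelope autocorrelation
# captures burst-train periodicity robustly under RR jitter
cardiacScores <- function(S, fs, maxPoints = 30000) {
  lagLo <- round(0.6 * fs); lagHi <- round(1.5 * fs)
  if (ncol(S) > maxPoints) S <- S[, seq_len(maxPoints), drop = FALSE]
  t(apply(S, 1, function(s) {
    ac <- stats::acf(s^2, lag.max = lagHi, plot = FALSE, demean = TRUE)$acf[-1]
    share <- sum(ac[lagLo:lagHi]^2) / max(sum(ac^2), 1e-12)
    c(acShare = share, kurtosis = excessKurtosis(s))
  }))
}

#' Recover the ICA-ECG and remove the cardiac field artifact
#'
#' Decomposes the EEG into independent components, designates the cardiac
#' component by the combined rank of (a) the share of autocorrelation energy
#' at heart-period lags (0.6-1.5 s) and (b) the excess kurtosis of the
#' component (QRS trains are spike-like), returns the component's source time
#' course as the ICA-ECG, and reconstructs the EEG with that component
#' removed. When the best candidate's kurtosis falls below
#' \code{minKurtosis}, no cardiac component is declared and an error advises
#' falling back to an externally recorded ECG channel.
#'
#' @param recording a [Recording-class] (>= 16 channels, >= 60 s).
#' @param nComp number of components (default: channel count).
#' @param seed seed for the deterministic ICA initialisation.
#' @param minKurtosis selection floor on the cardiac component's excess
#'   kurtosis (default 6).
#' @param maxIter,tol FastICA iteration controls.
#' @return list with \code{recording} (cleaned), \code{ecg} (ICA-ECG trace),
#'   \code{report} (component index, scores, convergence info).
#' @export
extractIcaEcg <- function(recording, nComp = nrow(recording@eeg), seed = 1,
                          minKurtosis = 6, maxIter = 200, tol = 1e-6) {
  if (nrow(recording@eeg) < 16) stop("extractIcaEcg: need at least 16 channels")
  if (ncol(recording@eeg) / recording@fs < 60)
    stop("extractIcaEcg: need at least 60 s of data for a stable decomposition")
  dec <- fastIcaDecomp(recording@eeg, nComp = nComp, seed = seed,
                       maxIter = maxIter, tol = tol)
  sc <- cardiacScores(dec$S, recording@fs)
  # candidates must be spike-train-like (kurtosis floor); among them the
  # combined rank of heart-period rhythmicity and kurtosis decides
  cand <- which(sc[, "kurtosis"] >= minKurtosis)
  if (!length(cand))
    stop("extractIcaEcg: no component passes the cardiac-selection criterion; ",
         "provide an external ECG channel instead")
  combRank <- rank(sc[, "acShare"]) + rank(sc[, "kurtosis"])
  j <- cand[which.max(combRank[cand])]
  ecg <- as.numeric(dec$S[j, ])
  cleaned <- recording@eeg - dec$A[, j, drop = FALSE] %*% dec$S[j, , drop = FALSE]
  rownames(cleaned) <- rownames(recording@eeg)
  out <- recording
  out@eeg <- cleaned
  out <- appendLog(out, sprintf("ica_ecg[component %d removed]", j))
  logMsg("preprocess", "cardiac component ", j, " (kurtosis ",
         sprintf("%.1f", sc[j, "kurtosis"]), ")")
  list(recording = out, ecg = ecg,
       report = list(cardiac_component_index = j,
                     cardiac_component_score = unname(combRank[j]),
                     component_scores = sc, converged = dec$converged,
                     iterations = dec$iterations))
}

# Legendre polynomials P_1..P_N evaluated at x (vectorised), as length(x) x N
legendreMatrix <- function(x, N) {
  P <- matrix(0, length(x), N)
  P[, 1] <- x
  if (N >= 2) P[, 2] <- (3 * x^2 - 1) / 2
  if (N >= 3) for (n in 2:(N - 1))
    P[, n + 1] <- ((2 * n + 1) * x * P[, n] - n * P[, n - 1]) / (n + 1)
  P
}

# spherical-spline kernel g(cos angle), order m, N Legendre terms
splineKernel <- function(cosang, m = 4, N = 20) {
  n <- seq_len(N)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  P <- legendreMatrix(pmin(pmax(cosang, -1), 1), N)
  as.numeric(P %*% coef) / (4 * pi)
}

# interpolate channel `bad` from channels `good` via spherical splines
sphericalSplineFit <- function(positions, good, bad, V, m = 4, lambda = 1e-5, N = 20) {
  U <- positions / sqrt(rowSums(positions^2))
  cosG <- tcrossprod(U[good, , drop = FALSE])
  G <- matrix(splineKernel(as.numeric(cosG), m = m, N = N), length(good))
  k <- length(good)
  M <- rbind(cbind(G + diag(lambda, k), rep(1, k)), c(rep(1, k), 0))
  rhs <- rbind(V, 0)
  sol <- solve(M, rhs)
  gb <- splineKernel(as.numeric(U[bad, , drop = FALSE] %*% t(U[good, , drop = FALSE])),
                     m = m, N = N)
  as.numeric(t(sol[seq_len(k), , drop = FALSE]) %*% gb + sol[k + 1, ])
}

#' Identify and interpolate low-correlation channels
#'
#' For each channel, Pearson correlations with its graph neighbours are
#' averaged with inverse-distance weights (inverse-square available);
#' channels whose weighted mean correlation falls below the threshold are
#' replaced by spherical-spline interpolation (order 4, regularisation 1e-5)
#' of their remaining neighbours. Channels without neighbours are never
#' interpolated (logged).
#'
#' @param recording a [Recording-class].
#' @param graph a [NeighborGraph-class] built on the recording's layout.
#' @param corrThreshold weighted-correlation floor (default 0.80).
#' @param weighting "inverse" (1/d, default) or "inverse_square" (1/d^2).
#' @param splineOrder,splineLambda,nLegendre spline parameters.
#' @return list with \code{recording} and \code{report} (interpolated channel
#'   names, per-channel weighted correlations, skipped isolated channels).
#' @export
interpolateLowCorrelationChannels <- function(recording, graph, corrThreshold = 0.80,
                                              weighting = c("inverse", "inverse_square"),
                                              splineOrder = 4, splineLambda = 1e-5,
                                              nLegendre = 20) {
  weighting <- match.arg(weighting)
  if (!identical(graph@channelNames, recording@layout@names))
    stop("interpolateLowCorrelationChannels: graph must be built on the recording's layout")
  eeg <- recording@eeg
  nCh <- nrow(eeg)
  d <- channelDistances(recording@layout)
  wfun <- if (weighting == "inverse") function(x) 1 / x else function(x) 1 / x^2
  wcorr <- rep(NA_real_, nCh)
  for (i in seq_len(nCh)) {
    nb <- graph@adjacency[[i]]
    if (!length(nb)) next
    r <- vapply(nb, function(j) suppressWarnings(cor(eeg[i, ], eeg[j, ])), 0)
    r[is.na(r)] <- 0
    w <- wfun(d[i, nb])
    wcorr[i] <- sum(w * r) / sum(w)
  }
  bad <- which(!is.na(wcorr) & wcorr < corrThreshold)
  isolated <- which(is.na(wcorr))
  if (length(bad) > nCh / 2)
    stop("interpolateLowCorrelationChannels: more than half the channels fall below ",
         "the correlation threshold (degenerate input)")
  out <- recording
  for (i in bad) {
    nb <- setdiff(graph@adjacency[[i]], bad)
    if (!length(nb)) next
    out@eeg[i, ] <- sphericalSplineFit(recording@layout@positions, nb, i,
                                       eeg[nb, , drop = FALSE], m = splineOrder,
                                       lambda = splineLambda, N = nLegendre)
  }
  out <- appendLog(out, sprintf("interp_corr[%d interpolated]", length(bad)))
  list(recording = out,
       report = list(interpolated_channels = recording@layout@names[bad],
                     weighted_correlations = stats::setNames(wcorr, recording@layout@names),
                     isolated_channels = recording@layout@names[isolated],
                     corr_threshold = corrThreshold, weighting = weighting))
}

#' Common-average re-reference and channel-subset selection
#'
#' Subtracts the per-sample mean over the retained channels (common average
#' reference), then extracts the requested subset in the given order. With
#' \code{subset = NULL} all channels are kept.
#'
#' @param recording a [Recording-class].
#' @param subset character vector of channel names to retain (e.g. a
#'   64-channel analysis montage); NULL keeps all channels.
#' @return re-referenced, subset [Recording-class].
#' @export
rereferenceAndSubset <- function(recording, subset = NULL) {
  eeg <- recording@eeg
  eeg <- sweep(eeg, 2, colMeans(eeg))
  out <- recording
  if (!is.null(subset)) {
    missing <- setdiff(subset, recording@layout@names)
    if (length(missing))
      stop("rereferenceAndSubset: subset channels missing: ", paste(missing, collapse = ", "))
    idx <- match(subset, recording@layout@names)
    eeg <- eeg[idx, , drop = FALSE]
    out@layout <- SensorLayout(recording@layout@names[idx],
                               recording@layout@positions[idx, , drop = FALSE])
  }
  out@eeg <- eeg
  appendLog(out, sprintf("car_subset[%d channels]", nrow(eeg)))
}
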