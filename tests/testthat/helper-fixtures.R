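# shared fixtures: toy layouts, quiet recordings with hand-placed events,
# and independent brute-force oracles for the resampling statistics

quietRecording <- function(nCh = 6, nSamples = 4000, fs = 250, events = NULL,
                           layout = NULL) {
  if (is.null(layout)) layout <- gridLayout(ceiling(nCh / 2), 2)
  layout <- SensorLayout(channelNames(layout)[seq_len(nCh)],
                         sensorPositions(layout)[seq_len(nCh), , drop = FALSE])
  if (is.null(events)) events <- emptyEvents()
  Recording(matrix(0, nCh, nSamples), fs, layout, events, subjectId = "toy")
}

# five-sound trial event rows with the 5th sound at `onset5` (0-based)
toyTrial <- function(onset5, trialId, condition, blockType = "XX", fs = 250) {
  soa <- round(150 * fs / 1000)
  data.frame(onset_sample = as.integer(onset5 - soa * (4:0)),
             trial_id = as.integer(trialId), sound_index = 1:5,
             block_type = blockType, condition = condition,
             stringsAsFactors = FALSE)
}

# brute-force neighbour computation: O(n^2) pairwise distances
oracleNeighbors <- function(layout, maxD) {
  pos <- sensorPositions(layout)
  n <- nrow(pos)
  lapply(seq_len(n), function(i) {
    which(vapply(seq_len(n), function(j)
      j != i && sqrt(sum((pos[i, ] - pos[j, ])^2)) <= maxD, logical(1)))
  })
}

# independent rank-sum Z (scalar, plain formula, base rank)
oracleRankSumZ <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  W <- sum(r[seq_len(n1)])
  tt <- table(r); tt <- tt[tt > 1]
  tie <- if (length(tt)) sum(tt^3 - tt) / (N * (N - 1)) else 0
  (W - n1 * (N + 1) / 2) / sqrt(n1 * n2 / 12 * ((N + 1) - tie))
}

# exhaustive-enumeration oracle for the cluster permutation: re-implements
# per-partition max-|Z|-over-mask from scratch (loops, base rank)
oraclePermutationStats <- function(mapsA, mapsB, alpha = 0.05) {
  X <- t(vapply(c(mapsA, mapsB), as.numeric, numeric(length(mapsA[[1]]))))
  N <- nrow(X); nA <- length(mapsA)
  zcrit <- qnorm(1 - alpha / 2)
  sets <- combn(N, nA)
  vapply(seq_len(ncol(sets)), function(k) {
    idx <- sets[, k]
    zmax <- 0
    for (j in seq_len(ncol(X))) {
      z <- oracleRankSumZ(X[idx, j], X[-idx, j])
      if (abs(z) > zcrit && abs(z) > zmax) zmax <- abs(z)
    }
    zmax
  }, 0)
}

# exact two-sided p of the rank-sum statistic by full enumeration
oracleExactRankSumP <- function(a, b) {
  r <- rank(c(a, b))
  n1 <- length(a); N <- length(r)
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (N + 1) / 2
  sets <- combn(N, n1)
  Ws <- colSums(matrix(r[sets], nrow = n1))
  mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
}

# exact two-sided p of the signed-rank statistic by sign enumeration
oracleExactSignedRankP <- function(values) {
  v <- values[values != 0]
  n <- length(v)
  r <- rank(abs(v))
  W <- sum(r[v > 0])
  EW <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
}
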