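#' @importFrom stats rnorm runif qnorm pnorm pt sd median mad cor quantile var dist pbinom setNames
#' @importFrom utils read.table write.table combn modifyList
NULL

# timestamped, stage-tagged logging; silenced unless option herclust.verbose
logMsg <- function(stage, ...) {
  if (isTRUE(getOption("herclust.verbose", FALSE))) {
    message(sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, paste0(...)))
  }
  invisible(NULL)
}

#' Derive a child RNG seed from a master seed and a stream label
#'
#' Deterministic splitting of one master seed into per-subject / per-stage
#' streams, so that whole-cohort analyses are reproducible from a single
#' integer. Always returns a non-negative integer below 2^31.
#'
#' @param seed master seed (integer).
#' @param ... labels (coerced to character) identifying the stream.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, ...) {
  lab <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(lab)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# trapezoidal integral with unit spacing scaled by dt
trapz <- function(y, dt = 1) {
  n <- length(y)
  if (n < 2) return(0)
  dt * sum((y[-1] + y[-n]) / 2)
}

#' Default analysis configuration
#'
#' One nested list mirroring every tunable of the pipeline: neighbourhood
#' distance, filter band and design, channel-rejection threshold, cardiac
#' component selection floor, interpolation settings, R-peak detection window
#' and refractory period, ectopic threshold, epoch rejection thresholds,
#' cluster-test alpha / minimum cluster size / partition count, surrogate
#' count, and classifier settings.
#'
#' @return named nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    neighbor = list(max_distance_cm = 4),
    filter = list(low_hz = 1, high_hz = 25, order = 4, mode = "iir"),
    reject = list(z_threshold = 3, max_iter = 10, auc_on = "abs"),
    ica = list(min_kurtosis = 6, max_iter = 200, tol = 1e-6),
    interp = list(corr_threshold = 0.80, weighting = "inverse",
                  spline_order = 4, spline_lambda = 1e-5, n_legendre = 20),
    rpeak = list(window_ms = 600, refractory_ms = 300, floor_frac = 0.4),
    ectopic = list(deriv_threshold = 3),
    epochs = list(amp_reject_uv = 300, ibi_floor_ms = 500, stim_guard_ms = 20,
                  erp_length_ms = 1000, her_length_ms = 500, baseline = FALSE,
                  guard_all_sounds = FALSE, pooling = "epochs"),
    cluster = list(alpha = 0.05, min_channels = 4, n_partitions = 10000),
    surrogate = list(n_surrogates = 100, n_partitions = 1000,
                     exceed_on = "effect"),
    stats = list(bonferroni_m = 8, median_test = "signed_rank"),
    classify = list(k = 5, priors = "equal", ridge = 1e-6)
  )
}

#' Read a YAML configuration file, merged over the defaults
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
readConfig <- function(path) {
  user <- yaml::read_yaml(path)
  mergeConfig(defaultConfig(), user)
}

mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]])) base[[k]] <- mergeConfig(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

# midrank-based ranks per column of a subjects x points matrix; one global
# rank call with per-column offsets large enough to keep columns separate
# (exact ties within a column stay exact ties)
colRanksMid <- function(X) {
  n <- nrow(X); m <- ncol(X)
  if (m == 1 || !all(is.finite(X)))
    return(apply(X, 2, rank, ties.method = "average"))
  span <- diff(range(X)) + 1
  off <- rep.int((seq_len(m) - 1) * span, rep.int(n, m))
  r <- rank(as.vector(X) + off, ties.method = "average")
  matrix(r - (rep.int(seq_len(m), rep.int(n, m)) - 1) * n, n, m)
}

# rank-sum normal-approximation machinery shared by zmapUnpaired and the
# permutation engine: given the rank matrix of the pooled sample, return the
# per-point expectation and standard deviation of the group-A rank sum,
# including the tie correction (ties are constant across permutations).
rankSumMoments <- function(R, nA) {
  N <- nrow(R)
  nB <- N - nA
  EW <- nA * (N + 1) / 2
  tieTerm <- numeric(ncol(R))
  hasTies <- which(apply(R, 2, anyDuplicated) > 0)
  for (j in hasTies) {
    tt <- tabulate(match(R[, j], unique(R[, j])))
    tt <- tt[tt > 1]
    tieTerm[j] <- if (length(tt)) sum(tt^3 - tt) else 0
  }
  VW <- nA * nB / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  list(EW = EW, sdW = sqrt(VW))
}

#' Unpaired Wilcoxon rank-sum Z for one pair of samples
#'
#' Normal approximation with midrank tie handling and no continuity
#' correction; orientation A minus B (positive Z when A tends larger).
#'
#' @param a,b numeric vectors.
#' @return list with components \code{Z}, \code{p} (two-sided), \code{W}.
#' @export
rankSumZ <- function(a, b) {
  r <- rank(c(a, b), ties.method = "average")
  nA <- length(a); N <- length(r)
  W <- sum(r[seq_len(nA)])
  m <- rankSumMoments(matrix(r, ncol = 1), nA)
  Z <- if (m$sdW > 0) (W - m$EW) / m$sdW else 0
  list(Z = Z, p = 2 * pnorm(-abs(Z)), W = W)
}

#' Wilcoxon signed-rank Z against zero
#'
#' Zeros dropped, midranks on |values|, tie-corrected normal approximation,
#' no continuity correction. The returned Z is signed by the direction of the
#' rank sum (positive when values tend positive).
#'
#' @param values numeric vector.
#' @return list with \code{Z}, \code{p} (two-sided), \code{W} (positive-rank sum),
#'   \code{n} (non-zero count).
#' @export
signedRankZ <- function(values) {
  v <- values[values != 0]
  n <- length(v)
  if (n == 0) stop("signedRankZ: all values are zero (degenerate)")
  r <- rank(abs(v), ties.method = "average")
  W <- sum(r[v > 0])
  EW <- n * (n + 1) / 4
  tt <- table(r)
  tt <- tt[tt > 1]
  tie <- if (!length(tt)) 0 else sum(tt^3 - tt) / 48
  VW <- n * (n + 1) * (2 * n + 1) / 24 - tie
  Z <- if (VW > 0) (W - EW) / sqrt(VW) else 0
  list(Z = Z, p = 2 * pnorm(-abs(Z)), W = W, n = n)
}
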