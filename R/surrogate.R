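#' @include AllClasses.R utils.R cardiac.R epochs.R cluster.R fastmaps.R
NULL

#' Generate surrogate heartbeat series by uniform re-timing
#'
#' Each surrogate reallocates every heartbeat timing uniformly at random
#' between the first and last sample of the recording, preserving the peak
#' count (collisions are redrawn). No minimum separation is enforced; the
#' downstream interbeat-interval and stimulus-guard epoch rules discard
#' implausible pairs as they would for real data.
#'
#' @param recording a [Recording-class] (sets the allowed sample span).
#' @param original the observed [HeartbeatSeries-class] (sets the count).
#' @param nSurrogates number of surrogates (default 100).
#' @param seed RNG seed.
#' @return list of [HeartbeatSeries-class] objects with source "SURROGATE".
#' @export
makeSurrogateHeartbeats <- function(recording, original, nSurrogates = 100, seed = 1) {
  nPeaks <- length(original@rpeakSamples)
  if (!nPeaks) stop("makeSurrogateHeartbeats: original series is empty")
  n <- ncol(recording@eeg)
  if (n < nPeaks) stop("makeSurrogateHeartbeats: recording shorter than the peak count")
  withSeed(seed, {
    lapply(seq_len(nSurrogates), function(s) {
      t <- sort(unique(floor(runif(nPeaks, 0, n))))
      while (length(t) < nPeaks)
        t <- sort(unique(c(t, floor(runif(nPeaks - length(t), 0, n)))))
      HeartbeatSeries(t, recording@fs, source = "SURROGATE")
    })
  })
}

bestSameSignCluster <- function(result, sign) {
  side <- Filter(function(cl) cl$sign == sign, result@clusters)
  if (!length(side)) return(NULL)
  side[[which.max(vapply(side, `[[`, 0, "stat"))]]
}

#' Monte Carlo p for an observed clustered effect against surrogates
#'
#' A surrogate counts as exceeding the observed cluster when BOTH its best
#' same-sign cluster matches or exceeds the observed cluster's measure AND
#' its cluster size, measured as distinct channel count (the unit cluster
#' sizes are expressed in throughout the analysis), is at least the observed
#' one (conjunction). The measure is the cluster max-|Z| statistic
#' (\code{exceedOn = "stat"}) or the absolute combined clustered effect
#' magnitude (\code{exceedOn = "effect"}). Surrogates without any same-sign
#' cluster never exceed. p = exceed count / number of surrogates.
#'
#' @param observed a [ClusterResult-class] with at least one cluster.
#' @param surrogates list of [ClusterResult-class], one per surrogate.
#' @param cluster which observed cluster to test (default: largest statistic).
#' @param exceedOn "stat" (default) or "effect".
#' @param effectsFn when \code{exceedOn = "effect"}, a function(clusterResult,
#'   cluster) returning the combined effect magnitude.
#' @param sizeOn size measure for the conjunction: "channels" (default) or
#'   "points" (channel x time member count).
#' @return list with \code{p}, \code{detail} (per-surrogate table), and the
#'   observed statistic and size.
#' @export
surrogateMcP <- function(observed, surrogates, cluster = NULL,
                         exceedOn = c("stat", "effect"), effectsFn = NULL,
                         sizeOn = c("channels", "points")) {
  exceedOn <- match.arg(exceedOn)
  sizeOn <- match.arg(sizeOn)
  if (!length(observed@clusters))
    stop("surrogateMcP: observed result has no clusters (nothing to test)")
  if (!length(surrogates)) stop("surrogateMcP: need at least one surrogate")
  if (is.null(cluster)) cluster <- observed@clusters[[1]]
  sizeOf <- function(cl) if (sizeOn == "channels") cl$nChannels else cl$size
  obsStat <- if (exceedOn == "stat") cluster$stat else abs(effectsFn(observed, cluster))
  obsSize <- sizeOf(cluster)
  detail <- do.call(rbind, lapply(seq_along(surrogates), function(s) {
    bc <- bestSameSignCluster(surrogates[[s]], cluster$sign)
    if (is.null(bc)) {
      data.frame(surrogate = s, stat = 0, size = 0, exceeds = FALSE)
    } else {
      st <- if (exceedOn == "stat") bc$stat else abs(effectsFn(surrogates[[s]], bc))
      data.frame(surrogate = s, stat = st, size = sizeOf(bc),
                 exceeds = st >= obsStat && sizeOf(bc) >= obsSize)
    }
  }))
  list(p = mean(detail$exceeds), detail = detail,
       observed_stat = obsStat, observed_size = obsSize)
}

#' Full surrogate-heartbeat specificity analysis of an HER effect
#'
#' Repeats the heartbeat-locked group analysis with randomly re-timed
#' heartbeats: per surrogate id, every subject's heartbeats are reallocated
#' (subject-specific derived seeds), HER epochs and subject contrast maps are
#' recomputed, and the group cluster-permutation test is re-run (at a reduced
#' partition count). The observed effect's Monte Carlo p is the proportion of
#' surrogates whose best same-sign cluster matches or exceeds it in both the
#' exceedance measure and the channel extent. When the observed analysis
#' yields no (significant) cluster the p is NA (there is no heartbeat-locked
#' effect to test).
#'
#' @param subjects list of per-subject lists with elements \code{recording}
#'   and \code{hb} (observed heartbeats).
#' @param groups character vector of group labels aligned with
#'   \code{subjects}; groupA/groupB select the contrasted sets.
#' @param level "LOCAL" or "GLOBAL".
#' @param graph a [NeighborGraph-class].
#' @param nSurrogates number of surrogate cohorts (default 100).
#' @param nPartitions partitions per cluster test (default 1000).
#' @param seed master seed.
#' @param groupA,groupB group labels (default MCS, UWS).
#' @param exceedOn exceedance measure: "effect" (default; the surrogate's best
#'   same-sign cluster must match or exceed the observed cluster in combined
#'   effect magnitude AND size) or "stat" (cluster max-|Z| statistic AND size).
#' @param targetCluster observed cluster to test: "significant" (default; the
#'   strongest cluster with Monte Carlo p < 0.05, mirroring that only
#'   reported clustered effects are submitted to the control; p is NA when no
#'   cluster is significant) or "best" (largest statistic regardless).
#' @param ... epoching overrides (ampRejectUv, ibiFloorMs, stimGuardMs,
#'   epochLengthMs), matching [epochHeartbeatPostStimulus()] semantics.
#' @return list with \code{p}, \code{observed} ([ClusterResult-class]),
#'   \code{detail} per-surrogate summaries.
#' @export
surrogateAnalysis <- function(subjects, groups, level, graph, nSurrogates = 100,
                              nPartitions = 1000, seed = 1, groupA = "MCS",
                              groupB = "UWS", exceedOn = c("effect", "stat"),
                              targetCluster = c("significant", "best"), ...) {
  exceedOn <- match.arg(exceedOn)
  targetCluster <- match.arg(targetCluster)
  fs <- subjects[[1]]$recording@fs
  herMaps <- function(hbList) {
    maps <- vector("list", length(subjects))
    for (i in seq_along(subjects)) {
      fm <- fastHerMaps(subjects[[i]]$recording, hbList[[i]], ...)
      if (is.null(fm) || is.null(fm[[level]])) return(NULL)
      maps[[i]] <- fm[[level]]
    }
    maps
  }
  iA <- which(groups == groupA); iB <- which(groups == groupB)
  # annotate every cluster with its combined-effect group difference
  # (magnitude of mean MCS combined effect minus mean UWS combined effect)
  annotate <- function(result, maps) {
    result@clusters <- lapply(result@clusters, function(cl) {
      ce <- combinedClusterEffect(maps, cl)
      cl$effectMag <- abs(mean(ce[iA]) - mean(ce[iB]))
      cl
    })
    result
  }
  obsMaps <- herMaps(lapply(subjects, `[[`, "hb"))
  if (is.null(obsMaps)) stop("surrogateAnalysis: observed epoching failed for a subject")
  observed <- permutationTest(obsMaps[iA], obsMaps[iB], graph,
                              nPartitions = nPartitions,
                              seed = deriveSeed(seed, "observed"), fs = fs)
  observed <- annotate(observed, obsMaps)
  detail <- vector("list", nSurrogates)
  surrogateResults <- vector("list", nSurrogates)
  for (s in seq_len(nSurrogates)) {
    hbS <- lapply(seq_along(subjects), function(i)
      makeSurrogateHeartbeats(subjects[[i]]$recording, subjects[[i]]$hb, 1,
                              seed = deriveSeed(seed, "surrogate", s, i))[[1]])
    mapsS <- herMaps(hbS)
    if (is.null(mapsS)) {
      surrogateResults[[s]] <- NULL
      next
    }
    surrogateResults[[s]] <- annotate(
      permutationTest(mapsS[iA], mapsS[iB], graph, nPartitions = nPartitions,
                      seed = deriveSeed(seed, "perm", s), fs = fs),
      mapsS)
    logMsg("surrogate", "surrogate ", s, " done")
  }
  ok <- !vapply(surrogateResults, is.null, logical(1))
  target <- if (identical(targetCluster, "significant")) {
    sig <- Filter(function(cl) !is.na(cl$mcP) && cl$mcP < 0.05, observed@clusters)
    if (length(sig)) sig[[which.max(vapply(sig, `[[`, 0, "stat"))]] else NULL
  } else {
    if (length(observed@clusters)) observed@clusters[[1]] else NULL
  }
  if (is.null(target)) {
    return(list(p = NA_real_, observed = observed, detail = NULL,
                note = "no (significant) observed cluster; nothing heartbeat-locked to test"))
  }
  mc <- surrogateMcP(observed, surrogateResults[ok], cluster = target,
                     exceedOn = exceedOn,
                     effectsFn = function(res, cl) cl$effectMag)
  list(p = mc$p, observed = observed, detail = mc$detail,
       n_surrogates_used = sum(ok))
}
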