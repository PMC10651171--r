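#' @include AllClasses.R utils.R
NULL

# stack a list of EffectMaps / matrices into subjects x points, recording dims
stackMaps <- function(maps) {
  mats <- lapply(maps, function(m) if (is(m, "EffectMap")) m@map else m)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("effect maps must share dimensions")
  v <- vapply(mats, as.numeric, numeric(prod(d)))
  X <- if (is.matrix(v)) t(v) else matrix(v, ncol = 1)
  list(X = X, nCh = d[1], nT = d[2])
}

#' Pointwise unpaired Wilcoxon rank-sum Z map between two groups
#'
#' Per (channel, time) point, the rank-sum Z value (normal approximation,
#' midrank ties, no continuity correction), oriented A minus B: positive Z
#' where group A tends larger. Pointwise two-sided p values come from the
#' normal reference.
#'
#' @param groupA,groupB lists of per-subject [EffectMap-class] objects (or
#'   plain channels x time matrices) with identical dimensions; at least 2
#'   subjects per group.
#' @return list with matrices \code{z} and \code{p} (channels x time).
#' @export
zmapUnpaired <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("zmapUnpaired: need at least 2 subjects per group")
  sa <- stackMaps(c(groupA, groupB))
  nA <- length(groupA)
  R <- colRanksMid(sa$X)
  mom <- rankSumMoments(R, nA)
  W <- colSums(R[seq_len(nA), , drop = FALSE])
  Z <- ifelse(mom$sdW > 0, (W - mom$EW) / mom$sdW, 0)
  z <- matrix(Z, sa$nCh, sa$nT)
  list(z = z, p = matrix(2 * pnorm(-abs(Z)), sa$nCh, sa$nT))
}

# connected components (BFS) among `nodes` under the graph adjacency
connectedComponents <- function(nodes, adj) {
  inSet <- logical(length(adj))
  inSet[nodes] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (v in nodes) {
    if (seen[v]) next
    queue <- v; seen[v] <- TRUE; comp <- integer(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      comp <- c(comp, u)
      nb <- adj[[u]]
      nb <- nb[inSet[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

#' Identify candidate spatiotemporal clusters in a Z map
#'
#' The preliminary mask is the set of points with pointwise p below alpha,
#' split by Z sign. Within each time sample, masked channels are grouped into
#' spatially connected components via the neighbour graph; components with
#' fewer than \code{minChannels} distinct channels are dropped. Surviving
#' same-sign components at adjacent time samples are merged ("wrapped") when
#' they share at least one channel, transitively across consecutive samples.
#'
#' @param zmap list with \code{z} and \code{p} matrices (from [zmapUnpaired()]).
#' @param graph a [NeighborGraph-class] whose channels match the map rows.
#' @param alpha pointwise mask threshold (default 0.05).
#' @param minChannels minimum distinct channels per component (default 4).
#' @param fs sampling rate for the latency annotation (Hz); default 250.
#' @return list of clusters, each a list with \code{members} (two-column
#'   matrix channel/time, 1-based), \code{sign}, \code{nChannels},
#'   \code{size}, \code{stat} (max |Z|), \code{latencyMs}, \code{mcP} (NA
#'   until a permutation test fills it).
#' @export
findCandidateClusters <- function(zmap, graph, alpha = 0.05, minChannels = 4, fs = 250) {
  z <- zmap$z; p <- zmap$p
  nT <- ncol(z)
  adj <- graph@adjacency
  # per time sample and sign: connected suprathreshold components
  comps <- list()
  for (t in seq_len(nT)) {
    for (sg in c(1, -1)) {
      nodes <- which(p[, t] < alpha & sign(z[, t]) == sg)
      if (length(nodes) < minChannels) next
      for (cc in connectedComponents(nodes, adj)) {
        if (length(cc) >= minChannels)
          comps[[length(comps) + 1]] <- list(t = t, sign = sg, channels = cc)
      }
    }
  }
  if (!length(comps)) return(list())
  # wrap same-sign components at adjacent time samples sharing >= 1 channel
  parent <- seq_along(comps)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(comps)) for (j in seq_along(comps)) {
    if (j <= i) next
    ci <- comps[[i]]; cj <- comps[[j]]
    if (ci$sign == cj$sign && abs(ci$t - cj$t) == 1 &&
        length(intersect(ci$channels, cj$channels)) >= 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_along(comps), find, 0L)
  out <- lapply(unique(roots), function(r) {
    grp <- comps[roots == r]
    members <- do.call(rbind, lapply(grp, function(g)
      cbind(channel = g$channels, time = g$t)))
    members <- unique(members)
    zs <- z[members]
    list(members = members, sign = if (grp[[1]]$sign > 0) "+" else "-",
         nChannels = length(unique(members[, "channel"])),
         size = nrow(members), stat = max(abs(zs)),
         latencyMs = (range(members[, "time"]) - 1) * 1000 / fs,
         mcP = NA_real_)
  })
  out[order(vapply(out, `[[`, 0, "stat"), decreasing = TRUE)]
}

# per-partition max-|Z| over the suprathreshold mask (0 when mask empty),
# given precomputed ranks and rank-sum moments; partitions are processed in
# chunks through one matrix product (partition indicator x rank matrix)
partitionStats <- function(R, nA, idxList, mom, zCrit, chunk = 1000) {
  N <- nrow(R)
  nP <- length(idxList)
  invSd <- ifelse(mom$sdW > 0, 1 / mom$sdW, 0)
  out <- numeric(nP)
  for (st in seq(1, nP, by = chunk)) {
    en <- min(st + chunk - 1, nP)
    P <- matrix(0, en - st + 1, N)
    for (k in st:en) P[k - st + 1, idxList[[k]]] <- 1
    W <- P %*% R
    Z <- abs((W - mom$EW) * rep(invSd, each = nrow(W)))
    m <- apply(Z, 1, max)
    out[st:en] <- ifelse(m > zCrit, m, 0)
  }
  out
}

#' Spatiotemporal cluster-permutation test between two groups
#'
#' Computes the observed Z map and candidate clusters, then refers each
#' cluster's statistic (max |Z| over its members) to a permutation null: for
#' each random partition of the pooled subjects into groups of the original
#' sizes, the partition statistic is the maximum |Z| over that partition's
#' own suprathreshold mask (0 when the mask is empty). The Monte Carlo p of a
#' cluster is the proportion of partitions whose statistic is at least the
#' cluster's (ties count as exceedances). When the number of distinct
#' partitions does not exceed \code{nPartitions}, all partitions are
#' enumerated instead of sampled.
#'
#' @param effectsA,effectsB lists of per-subject [EffectMap-class] objects or
#'   matrices (>= 2 per group).
#' @param graph a [NeighborGraph-class].
#' @param nPartitions number of random partitions (default 10000; < 100 warns).
#' @param seed RNG seed for partition sampling.
#' @param alpha pointwise mask alpha (default 0.05).
#' @param minChannels minimum cluster extent in channels (default 4).
#' @param fs sampling rate for latency annotation (Hz).
#' @param clusterWithinPermutations also apply the min-channel and wrapping
#'   rules inside each permutation (sensitivity analysis; default FALSE).
#' @return A [ClusterResult-class].
#' @export
permutationTest <- function(effectsA, effectsB, graph, nPartitions = 10000,
                            seed = 1, alpha = 0.05, minChannels = 4, fs = 250,
                            clusterWithinPermutations = FALSE) {
  if (nPartitions < 1) stop("permutationTest: nPartitions must be at least 1")
  if (nPartitions < 100) warning("permutationTest: fewer than 100 partitions")
  if (length(effectsA) < 2 || length(effectsB) < 2)
    stop("permutationTest: need at least 2 subjects per group")
  nA <- length(effectsA); nB <- length(effectsB); N <- nA + nB
  sa <- stackMaps(c(effectsA, effectsB))
  R <- colRanksMid(sa$X)
  mom <- rankSumMoments(R, nA)
  Wobs <- colSums(R[seq_len(nA), , drop = FALSE])
  Zobs <- ifelse(mom$sdW > 0, (Wobs - mom$EW) / mom$sdW, 0)
  zobs <- list(z = matrix(Zobs, sa$nCh, sa$nT),
               p = matrix(2 * pnorm(-abs(Zobs)), sa$nCh, sa$nT))
  clusters <- findCandidateClusters(zobs, graph, alpha = alpha,
                                    minChannels = minChannels, fs = fs)
  zCrit <- qnorm(1 - alpha / 2)
  nDistinct <- choose(N, nA)
  exhaustive <- nDistinct <= nPartitions
  idxList <- if (exhaustive) {
    cmb <- combn(N, nA)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    withSeed(seed, replicate(nPartitions, sample.int(N, nA), simplify = FALSE))
  }
  perm <- if (clusterWithinPermutations) {
    vapply(idxList, function(idx) {
      W <- colSums(R[idx, , drop = FALSE])
      Z <- ifelse(mom$sdW > 0, (W - mom$EW) / mom$sdW, 0)
      zm <- list(z = matrix(Z, sa$nCh, sa$nT),
                 p = matrix(2 * pnorm(-abs(Z)), sa$nCh, sa$nT))
      cls <- findCandidateClusters(zm, graph, alpha = alpha,
                                   minChannels = minChannels, fs = fs)
      if (length(cls)) max(vapply(cls, `[[`, 0, "stat")) else 0
    }, 0)
  } else {
    partitionStats(R, nA, idxList, mom, zCrit)
  }
  nP <- length(idxList)
  for (k in seq_along(clusters))
    clusters[[k]]$mcP <- mean(perm >= clusters[[k]]$stat)
  new("ClusterResult", z = zobs$z, p = zobs$p, clusters = clusters,
      permDistribution = perm, nPartitions = nP, exhaustive = exhaustive,
      seed = as.numeric(seed), combinedEffects = data.frame(), fs = fs,
      channelNames = graph@channelNames)
}

#' Per-subject combined clustered effect
#'
#' The unweighted mean of a subject's contrast map over a cluster's member
#' points (channel x time), collapsing the cluster to one scalar per subject.
#'
#' @param effects list of per-subject [EffectMap-class] objects or matrices.
#' @param cluster one cluster from a [ClusterResult-class].
#' @return named numeric vector, one value per subject (microvolts).
#' @export
combinedClusterEffect <- function(effects, cluster) {
  if (is.null(cluster) || !nrow(cluster$members)) stop("combinedClusterEffect: empty cluster")
  vapply(effects, function(m) {
    mm <- if (is(m, "EffectMap")) m@map else m
    mean(mm[cluster$members])
  }, 0)
}

#' Combined effect over the significant clusters of a test, per subject
#'
#' When a test yields both positive and negative significant clusters, the
#' pairing value is mean over positive-cluster points minus mean over
#' negative-cluster points; with a single sign the value is that side alone.
#' The per-sign components are returned as attributes.
#'
#' @param effects list of per-subject maps.
#' @param result a [ClusterResult-class].
#' @param alpha Monte Carlo significance level (default 0.05); clusters with
#'   \code{mcP < alpha} enter. With no significant cluster, NA values return.
#' @return numeric vector per subject, with attributes "positive"/"negative".
#' @export
combinedSignificantEffect <- function(effects, result, alpha = 0.05) {
  sig <- Filter(function(cl) !is.na(cl$mcP) && cl$mcP < alpha, result@clusters)
  n <- length(effects)
  if (!length(sig)) {
    out <- rep(NA_real_, n)
    return(out)
  }
  best <- function(sgn) {
    side <- Filter(function(cl) cl$sign == sgn, sig)
    if (!length(side)) return(NULL)
    side[[which.max(vapply(side, `[[`, 0, "stat"))]]
  }
  pos <- best("+"); neg <- best("-")
  vPos <- if (!is.null(pos)) combinedClusterEffect(effects, pos) else NULL
  vNeg <- if (!is.null(neg)) combinedClusterEffect(effects, neg) else NULL
  out <- if (!is.null(vPos) && !is.null(vNeg)) vPos - vNeg
         else if (!is.null(vPos)) vPos else vNeg
  attr(out, "positive") <- vPos
  attr(out, "negative") <- vNeg
  out
}
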