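#' @include AllClasses.R utils.R simulate.R cluster.R surrogate.R fastmaps.R preprocess.R cardiac.R classify.R stats.R
NULL

# The resampling studies below fix the package's scaled study conditions
# (cohort sizes, montages, trial counts, partition counts); the methods
# vignette documents each choice. They are used both by the test suite and
# by the acceptance script.

#' Type-I-error calibration of the cluster-permutation test
#'
#' Simulates null cohorts (no group difference) of subject-level effect maps
#' with EEG-like spatiotemporal correlation on a planar 4 x 4 grid montage
#' and records, per cohort, whether any cluster reaches Monte Carlo
#' significance.
#'
#' @param nCohorts number of simulated cohorts (default 200).
#' @param nA,nB group sizes (default 20 and 20).
#' @param nChannels grid channel count (default 16).
#' @param nTime map length in samples (default 50).
#' @param nPartitions partitions per test (default 500).
#' @param alpha cluster significance level (default 0.05).
#' @param seed master seed.
#' @return list with \code{fpr} (dataset-level false-positive rate) and
#'   \code{positives} (per-cohort logical).
#' @export
nullCalibrationStudy <- function(nCohorts = 200, nA = 20, nB = 20, nChannels = 16,
                                 nTime = 50, nPartitions = 500, alpha = 0.05,
                                 seed = 1) {
  side <- ceiling(sqrt(nChannels))
  lay <- gridLayout(side, side)
  lay <- SensorLayout(lay@names[seq_len(nChannels)],
                      lay@positions[seq_len(nChannels), , drop = FALSE])
  graph <- buildNeighborGraph(lay, 4)
  pos <- vapply(seq_len(nCohorts), function(i) {
    mp <- simulateEffectMaps(nA, nB, lay, nTime, seed = deriveSeed(seed, "cal", i))
    r <- permutationTest(mp$A, mp$B, graph, nPartitions = nPartitions,
                         seed = deriveSeed(seed, "calperm", i), alpha = alpha)
    any(vapply(r@clusters, function(cl) cl$mcP < alpha, logical(1)))
  }, logical(1))
  list(fpr = mean(pos), positives = pos)
}

# simulate a two-group patient cohort and return per-subject fast maps;
# recordings are dropped as soon as their maps are computed to bound memory
simulateGroupMaps <- function(cfg, nMcs, nUws, seed, useDetectedPeaks = TRUE) {
  groups <- rep(c("MCS", "UWS"), c(nMcs, nUws))
  maps <- lapply(seq_along(groups), function(i) {
    s <- simulateSubject(cfg, groups[i], seed = deriveSeed(seed, "subj", i),
                         subjectId = sprintf("s%02d", i))
    hb <- if (useDetectedPeaks) {
      h <- detectRPeaks(s$truth$ecg, cfg$fs)
      if (length(h@ibiMs) >= 3) flagEctopic(h) else h
    } else HeartbeatSeries(s$truth$true_rpeak_samples, cfg$fs, source = "TRUE")
    c(fastErpMaps(s$recording), her = fastHerMaps(s$recording, hb))
  })
  list(maps = maps, groups = groups)
}

#' Planted-effect recovery study
#'
#' Simulates scaled patient cohorts (18 MCS-like vs 18 UWS-like, 48-channel
#' cap, 2 XX + 2 XY blocks of 40 trials) with the group effects planted in
#' the canonical windows (ERP local 236-328 ms, ERP global 800-850 ms, HER
#' local 400-412 ms, HER global 112-130 ms), runs the four group
#' cluster-permutation tests per seed, and records whether a significant
#' cluster overlaps each planted window (channel and latency). It also
#' evaluates the qualitative group pattern: global combined effects
#' significantly non-zero (signed-rank, Bonferroni alpha 0.05/8) in the
#' MCS-like group only.
#'
#' @param nSeeds number of simulated cohorts (default 20).
#' @param nPerGroup subjects per group (default 18).
#' @param nChannels cap channels (default 48).
#' @param trialsPerBlock trials per block (default 40).
#' @param nPartitions partitions per test (default 500).
#' @param seed master seed.
#' @return list with \code{recovery} (per effect, fraction of seeds with an
#'   overlapping significant cluster), \code{patternRate} (fraction of seeds
#'   with the global-effect group pattern for both signals), and the
#'   per-seed detail data.frame.
#' @export
plantedRecoveryStudy <- function(nSeeds = 20, nPerGroup = 18, nChannels = 48,
                                 trialsPerBlock = 40, nPartitions = 500, seed = 1) {
  cfg <- simConfig(n_channels = nChannels, trials_per_block = trialsPerBlock)
  layout <- simLayout(cfg)
  graph <- buildNeighborGraph(layout, 4)
  effCh <- simEffectChannels(layout, graph, cfg$n_effect_channels)
  wins <- list(ERP_LOCAL = cfg$erp_local_window_ms, ERP_GLOBAL = cfg$erp_global_window_ms,
               HER_LOCAL = cfg$her_local_window_ms, HER_GLOBAL = cfg$her_global_window_ms)
  keyOf <- list(ERP_LOCAL = "LOCAL", ERP_GLOBAL = "GLOBAL",
                HER_LOCAL = "her.LOCAL", HER_GLOBAL = "her.GLOBAL")
  detail <- NULL
  for (s in seq_len(nSeeds)) {
    gm <- simulateGroupMaps(cfg, nPerGroup, nPerGroup, deriveSeed(seed, "rec", s))
    iA <- which(gm$groups == "MCS"); iB <- which(gm$groups == "UWS")
    for (key in names(wins)) {
      mapsAll <- lapply(gm$maps, `[[`, keyOf[[key]])
      r <- permutationTest(mapsAll[iA], mapsAll[iB], graph, nPartitions = nPartitions,
                           seed = deriveSeed(seed, "perm", s, key), fs = cfg$fs)
      sig <- Filter(function(cl) cl$mcP < 0.05, r@clusters)
      overlap <- any(vapply(sig, function(cl) {
        tms <- (cl$members[, "time"] - 1) * 1000 / cfg$fs
        any(cl$members[, "channel"] %in% effCh &
              tms >= wins[[key]][1] & tms <= wins[[key]][2])
      }, logical(1)))
      comb <- combinedSignificantEffect(mapsAll, r)
      pv <- function(ii) {
        v <- comb[ii]
        if (all(is.na(v))) NA_real_
        else medianVsZeroTest(v[!is.na(v)])$p
      }
      detail <- rbind(detail, data.frame(
        seed = s, effect = key, n_sig_clusters = length(sig), overlap = overlap,
        p_mcs = pv(iA), p_uws = pv(iB), stringsAsFactors = FALSE))
    }
    logMsg("study", "recovery seed ", s, " done")
  }
  alphaB <- 0.05 / 8
  recovery <- tapply(detail$overlap, detail$effect, mean)
  glob <- detail[detail$effect %in% c("ERP_GLOBAL", "HER_GLOBAL"), ]
  patt <- tapply(seq_len(nrow(glob)), glob$seed, function(ii)
    all(!is.na(glob$p_mcs[ii]) & glob$p_mcs[ii] < alphaB) &&
      all(is.na(glob$p_uws[ii]) | glob$p_uws[ii] >= alphaB))
  list(recovery = recovery, patternRate = mean(patt), detail = detail)
}

#' Surrogate-heartbeat specificity study
#'
#' Simulates scaled cohorts (12 MCS-like vs 12 UWS-like, 5 x 5 grid montage,
#' 2 XX + 2 XY blocks of 40 trials) under one of two scenarios: "heartbeat"
#' (group effects locked to the heartbeats following the 5th sound; stimulus
#' effects absent) or "stimulus" (the standard stimulus-locked group effects
#' and no heartbeat-locked one). Per run, the observed HER analysis (local
#' level in the "heartbeat" scenario, global level in the "stimulus" one,
#' mirroring the significant and non-significant analogues) is compared
#' against uniformly re-timed surrogate heartbeats. A run without
#' any observed cluster yields p = NA, summarised as maximally
#' non-significant (p = 1).
#'
#' @param scenario "heartbeat" or "stimulus".
#' @param nRuns number of seeded runs (default 10).
#' @param nSurrogates surrogates per run (default 50).
#' @param nPartitions partitions per cluster test (default 500).
#' @param nPerGroup subjects per group (default 12).
#' @param trialsPerBlock trials per block (default 40).
#' @param seed master seed.
#' @return list with \code{p} (per-run surrogate p, NA when no observed
#'   cluster) and \code{pFilled} (NA replaced by 1).
#' @export
surrogateSpecificityStudy <- function(scenario = c("heartbeat", "stimulus"),
                                      nRuns = 10, nSurrogates = 50,
                                      nPartitions = 500, nPerGroup = 12,
                                      trialsPerBlock = 40, seed = 1) {
  scenario <- match.arg(scenario)
  cfg <- if (scenario == "heartbeat") {
    simConfig(layout_type = "grid", n_channels = 25, trials_per_block = trialsPerBlock,
              erp_local_amp = 0, erp_global_amp = 0)
  } else {
    # stimulus-locked effects at the standard study amplitude, nothing locked
    # to the heartbeats
    simConfig(layout_type = "grid", n_channels = 25, trials_per_block = trialsPerBlock,
              her_local_amp = 0, her_global_amp = 0)
  }
  layout <- simLayout(cfg)
  graph <- buildNeighborGraph(layout, 4)
  # the significant analogue is the HER local effect; the non-significant
  # analogue is the HER global effect
  level <- if (scenario == "heartbeat") "LOCAL" else "GLOBAL"
  groups <- rep(c("MCS", "UWS"), c(nPerGroup, nPerGroup))
  ps <- vapply(seq_len(nRuns), function(run) {
    runSeed <- deriveSeed(seed, scenario, run)
    subj <- lapply(seq_along(groups), function(i) {
      s <- simulateSubject(cfg, groups[i], seed = deriveSeed(runSeed, "subj", i),
                           subjectId = sprintf("s%02d", i))
      hb <- detectRPeaks(s$truth$ecg, cfg$fs)
      if (length(hb@ibiMs) >= 3) hb <- flagEctopic(hb)
      list(recording = s$recording, hb = hb)
    })
    res <- surrogateAnalysis(subj, groups, level, graph,
                             nSurrogates = nSurrogates, nPartitions = nPartitions,
                             seed = deriveSeed(seed, "surr", scenario, run))
    logMsg("study", "surrogate run ", run, " (", scenario, "): p = ", format(res$p))
    res$p
  }, 0)
  list(p = ps, pFilled = ifelse(is.na(ps), 1, ps))
}

#' ICA-ECG R-peak fidelity study
#'
#' Simulates single subjects (24-channel cap, 1 XX + 1 XY block of 25
#' trials), recovers the ICA-ECG from the cardiac field artifact, detects
#' R-peaks on it, and measures agreement with the ground-truth peak times.
#'
#' @param nSubjects number of subjects (default 20).
#' @param toleranceSamples match tolerance (default 1 sample, 4 ms at 250 Hz).
#' @param seed master seed.
#' @return data.frame per subject: matched fraction of true peaks, false
#'   positives outside tolerance, peak counts.
#' @export
rpeakFidelityStudy <- function(nSubjects = 20, toleranceSamples = 1, seed = 1) {
  cfg <- simConfig(n_channels = 24, trials_per_block = 25)
  out <- lapply(seq_len(nSubjects), function(i) {
    s <- simulateSubject(cfg, c("MCS", "UWS")[1 + i %% 2],  # group irrelevant here
                         seed = deriveSeed(seed, "fid", i))
    ic <- extractIcaEcg(s$recording, seed = deriveSeed(seed, "ica", i))
    hb <- detectRPeaks(ic$ecg, cfg$fs)
    truth <- s$truth$true_rpeak_samples
    det <- hb@rpeakSamples
    matched <- mean(vapply(truth, function(p) min(abs(p - det)) <= toleranceSamples,
                           logical(1)))
    falsePos <- sum(vapply(det, function(p) min(abs(p - truth)) > toleranceSamples,
                           logical(1)))
    data.frame(subject = i, matched = matched, false_positives = falsePos,
               n_true = length(truth), n_detected = length(det))
  })
  do.call(rbind, out)
}

#' Classification pattern study on simulated combined-effect features
#'
#' Draws feature tables following the group pattern of the combined clustered
#' effects and summarises quad-versus-triad fivefold LDA accuracy across
#' seeds.
#'
#' @param nSeeds number of feature cohorts (default 20).
#' @param nMcs,nUws class sizes (default 46 and 40).
#' @param seed master seed.
#' @return data.frame per seed: quad accuracy, median and max triad accuracy.
#' @export
classificationStudy <- function(nSeeds = 20, nMcs = 46, nUws = 40, seed = 1) {
  out <- lapply(seq_len(nSeeds), function(i) {
    feat <- simulateFeatureTable(nMcs, nUws, seed = deriveSeed(seed, "feat", i))
    reports <- runAllSubsets(feat, seed = deriveSeed(seed, "cv", i))
    acc <- vapply(reports, `[[`, 0, "accuracy")
    data.frame(seed = i, quad = acc[["quad"]],
               triad_median = median(acc[names(acc) != "quad"]),
               triad_max = max(acc[names(acc) != "quad"]))
  })
  do.call(rbind, out)
}
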