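#' @include AllClasses.R utils.R neighbors.R
NULL

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration for a synthetic local-global cohort
#'
#' Defaults reproduce the protocol conditions of the local-global paradigm as
#' run in disorders-of-consciousness studies: 250 Hz EEG, 64 channels on a
#' hemispherical cap, five 50-ms tones per trial at 150 ms onset asynchrony,
#' 1350-1650 ms intertrial interval, ~80/20 frequent/rare trials, patients
#' with 2 XX + 2 XY blocks of ~90 trials (about 200 s per block), controls
#' with 1 + 1 blocks, and cohort sizes 46 MCS / 40 UWS / 11 controls.
#' Planted group effects live in the windows where the corresponding
#' stimulus- and heartbeat-locked group differences are observed (ERP local
#' 236-328 ms, ERP global 800-850 ms, HER local 400-412 ms, HER global
#' 112-130 ms post lock). Amplitudes default to half the single-epoch noise
#' SD (per-epoch SNR 0.5). UWS-like subjects receive the local effects at a
#' reduced factor and null global effects; MCS-like subjects additionally
#' receive inflated trial-to-trial heartbeat-locked variability.
#'
#' @param ... overrides of any default field.
#' @return named list of simulation parameters (class "herclust_simconfig").
#' @export
simConfig <- function(...) {
  cfg <- list(
    n_mcs = 46, n_uws = 40, n_control = 11,
    n_blocks_xx = 2, n_blocks_xy = 2, trials_per_block = 90,
    control_blocks_xx = 1, control_blocks_xy = 1,
    fs = 250, n_channels = 64, cap_radius_cm = 9, layout_type = "cap",
    grid_spacing_cm = 3,
    rare_fraction = 0.2, tone_duration_ms = 50, soa_ms = 150,
    iti_range_ms = c(1350, 1650),
    lead_in_s = 2, block_gap_s = 5, tail_s = 2,
    rr_mean_ms = 800, rr_sd_ms = 60, rr_floor_ms = 250,
    artifact_gain = 60,
    noise_sd_uv = 10, noise_model = "ar1", ar_coef = 0.9, spatial_mix = 0.95,
    spatial_passes = 5, noise_rank = 16,
    erp_local_amp = 5, erp_local_window_ms = c(236, 328),
    erp_global_amp = 5, erp_global_window_ms = c(800, 850),
    her_local_amp = 5, her_local_window_ms = c(400, 412),
    her_global_amp = 5, her_global_window_ms = c(112, 130),
    her_trial_variance_ratio = 2, her_variability_sd = 2,
    uws_erp_local_factor = 0.4, uws_her_local_factor = -0.4,
    uws_global_factor = 0,
    n_effect_channels = 8,
    seed = 1L
  )
  cfg <- mergeConfig(cfg, list(...))
  stopifnot(cfg$rare_fraction > 0, cfg$rare_fraction < 1,
            cfg$iti_range_ms[1] <= cfg$iti_range_ms[2],
            all(is.finite(c(cfg$erp_local_amp, cfg$erp_global_amp,
                            cfg$her_local_amp, cfg$her_global_amp))))
  stopifnot(cfg$rr_mean_ms > cfg$rr_floor_ms)
  class(cfg) <- "herclust_simconfig"
  cfg
}

#' Hemispherical sensor cap layout
#'
#' Deterministic Fibonacci arrangement of n sensors on the upper hemisphere
#' of a cap of the given radius, giving realistic inter-channel distances for
#' a 4 cm neighbourhood.
#'
#' @param n number of channels.
#' @param radiusCm cap radius in cm (default 9).
#' @return A [SensorLayout-class].
#' @export
hemisphericalLayout <- function(n, radiusCm = 9) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # uniform in (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))    # golden-angle azimuth
  r <- sqrt(1 - z^2)
  pos <- radiusCm * cbind(r * cos(phi), r * sin(phi), z)
  SensorLayout(sprintf("E%03d", seq_len(n)), pos)
}

#' Planar grid sensor layout
#'
#' Regular nx x ny grid at the given spacing (cm) in the z = 0 plane, row
#' major. Useful as a dense, spatially regular montage for map-level
#' calibration studies where every channel has orthogonal neighbours.
#'
#' @param nx,ny grid dimensions.
#' @param spacingCm inter-channel spacing in cm (default 3).
#' @return A [SensorLayout-class].
#' @export
gridLayout <- function(nx, ny, spacingCm = 3) {
  pos <- expand.grid(x = (seq_len(nx) - 1) * spacingCm,
                     y = (seq_len(ny) - 1) * spacingCm)
  SensorLayout(sprintf("G%02d", seq_len(nx * ny)), cbind(pos$x, pos$y, 0))
}

#' Channel plus its graph neighbours (a spatially contiguous set)
#'
#' Convenience selector for planting spatially clustered effects: the given
#' channel and its neighbours under the graph, truncated to \code{n}.
#'
#' @param graph a [NeighborGraph-class].
#' @param center channel index.
#' @param n maximum set size.
#' @return integer channel indices.
#' @export
contiguousChannelSet <- function(graph, center, n) {
  set <- center
  frontier <- center
  while (length(set) < n && length(frontier)) {
    nxt <- setdiff(sort(unique(unlist(graph@adjacency[frontier]))), set)
    set <- c(set, nxt)
    frontier <- nxt
  }
  sort(set[seq_len(min(n, length(set)))])
}

# montage implied by a simulation config
simLayout <- function(cfg) {
  if (identical(cfg$layout_type, "grid")) {
    nx <- ceiling(sqrt(cfg$n_channels))
    ny <- ceiling(cfg$n_channels / nx)
    lay <- gridLayout(nx, ny, cfg$grid_spacing_cm)
    SensorLayout(lay@names[seq_len(cfg$n_channels)],
                 lay@positions[seq_len(cfg$n_channels), , drop = FALSE])
  } else {
    hemisphericalLayout(cfg$n_channels, cfg$cap_radius_cm)
  }
}

# spatially contiguous planted-effect channel set around the montage centre
# (cap apex, or the channel nearest the planar centroid)
simEffectChannels <- function(layout, graph, n) {
  pos <- layout@positions
  center <- if (diff(range(pos[, 3])) > 0) which.max(pos[, 3])
            else which.min(colSums((t(pos) - colMeans(pos))^2))
  contiguousChannelSet(graph, center, n)
}

#' Generate the auditory event stream of one block
#'
#' Each trial is five tones at the configured stimulus-onset asynchrony; the
#' intertrial interval (5th-tone offset to next 1st-tone onset) is uniform on
#' the configured range. Condition labels follow the block semantics:
#' XX frequent -> LSGS, XX rare -> LDGD, XY frequent -> LDGS, XY rare -> LSGD.
#' The number of rare trials is round(rareFraction * trials), at seeded
#' uniformly random trial positions.
#'
#' @param blockType "XX" or "XY".
#' @param trialsPerBlock number of trials (>= 1).
#' @param rareFraction proportion of rare trials, in (0, 1).
#' @param timing list with fs, tone_duration_ms, soa_ms, iti_range_ms.
#' @param seed RNG seed.
#' @param startSample 0-based sample at which the first trial starts.
#' @param trialIdOffset added to trial ids (for multi-block streams).
#' @return list with \code{events} (data.frame) and \code{endSample} (first
#'   sample after the block's last tone offset).
#' @export
generateEventStream <- function(blockType, trialsPerBlock, rareFraction, timing,
                                seed = 1, startSample = 0, trialIdOffset = 0) {
  stopifnot(blockType %in% BLOCK_LEVELS)
  if (trialsPerBlock < 1) stop("generateEventStream: trialsPerBlock must be >= 1")
  if (rareFraction <= 0 || rareFraction >= 1)
    stop("generateEventStream: rareFraction must lie in (0, 1)")
  fs <- timing$fs
  toneSmp <- round(timing$tone_duration_ms * fs / 1000)
  nRare <- round(rareFraction * trialsPerBlock)
  withSeed(seed, {
    rareIdx <- sort(sample(seq_len(trialsPerBlock), nRare))
    itis <- runif(trialsPerBlock, timing$iti_range_ms[1], timing$iti_range_ms[2])
    freqCond <- if (blockType == "XX") "LSGS" else "LDGS"
    rareCond <- if (blockType == "XX") "LDGD" else "LSGD"
    # onsets tracked in continuous ms and quantised per sound, so within-trial
    # spacing stays exactly one SOA up to single-sample rounding
    onsetMs <- numeric(0); trial <- integer(0); sound <- integer(0); cond <- character(0)
    tMs <- startSample * 1000 / fs
    for (tr in seq_len(trialsPerBlock)) {
      on5 <- tMs + timing$soa_ms * (0:4)
      onsetMs <- c(onsetMs, on5)
      trial <- c(trial, rep(tr + trialIdOffset, 5))
      sound <- c(sound, 1:5)
      cond <- c(cond, rep(if (tr %in% rareIdx) rareCond else freqCond, 5))
      tMs <- on5[5] + timing$tone_duration_ms + itis[tr]
    }
    ev <- data.frame(onset_sample = as.integer(round(onsetMs * fs / 1000)),
                     trial_id = trial, sound_index = sound, block_type = blockType,
                     condition = cond, stringsAsFactors = FALSE)
    list(events = ev, endSample = ev$onset_sample[nrow(ev)] + toneSmp)
  })
}

# 80 ms biphasic QRS-like template whose global maximum is a single sample
qrsTemplate <- function(fs) {
  tMs <- seq(0, 80, by = 1000 / fs)
  peak <- exp(-((tMs - 40) / 6)^2)
  trough <- -0.35 * exp(-((tMs - 58) / 10)^2)
  w <- peak + trough
  w / max(w)
}

#' Simulate an ECG-like trace with RR-variable heartbeats
#'
#' Interbeat intervals are drawn from a normal distribution truncated at
#' +/- 3 SD and at a positivity floor; a fixed biphasic QRS-like template is
#' placed at each beat so that the R-peak is the template's global maximum.
#'
#' @param durationS trace duration in seconds (> 0).
#' @param fs sampling rate (Hz).
#' @param rrMeanMs,rrSdMs interbeat interval mean and SD (ms).
#' @param seed RNG seed.
#' @param rrFloorMs positivity floor for the truncation (ms).
#' @return list with \code{ecg} (numeric trace, unit peak amplitude),
#'   \code{rpeaks} (0-based true R-peak samples), \code{fs}.
#' @export
simulateCardiac <- function(durationS, fs, rrMeanMs, rrSdMs, seed = 1,
                            rrFloorMs = 250) {
  if (durationS <= 0) stop("simulateCardiac: duration must be positive")
  if (rrMeanMs <= 0) stop("simulateCardiac: rrMeanMs must be positive")
  if (rrSdMs < 0) stop("simulateCardiac: rrSdMs must be non-negative")
  n <- round(durationS * fs)
  lo <- max(rrFloorMs, rrMeanMs - 3 * rrSdMs)
  hi <- rrMeanMs + 3 * rrSdMs
  withSeed(seed, {
    tMs <- rrMeanMs / 2
    peaksMs <- numeric(0)
    while (tMs < durationS * 1000) {
      peaksMs <- c(peaksMs, tMs)
      ib <- if (rrSdMs == 0) rrMeanMs else {
        repeat {
          cand <- rnorm(1, rrMeanMs, rrSdMs)
          if (cand >= lo && cand <= hi) break
        }
        cand
      }
      tMs <- tMs + ib
    }
    w <- qrsTemplate(fs)
    ipk <- which.max(w) - 1L
    peaks <- round(peaksMs * fs / 1000)
    peaks <- peaks[peaks - ipk >= 0 & peaks - ipk + length(w) - 1 < n]
    ecg <- numeric(n)
    for (p in peaks) {
      idx <- (p - ipk):(p - ipk + length(w) - 1) + 1L
      ecg[idx] <- ecg[idx] + w
    }
    list(ecg = ecg, rpeaks = as.numeric(peaks), fs = fs)
  })
}

# smooth unit-peak bump over a sample window: half-sine evaluated at sample
# midpoints, so short windows still carry amplitude at every sample
windowBump <- function(len) {
  if (len <= 1) return(rep(1, max(1, len)))
  sin(pi * (seq_len(len) - 0.5) / len)
}

# channels x samples matrix of EEG-like background noise: AR(1) in time and,
# through repeated neighbour averaging, strongly correlated across nearby
# channels (emulating volume conduction; neighbour correlations ~ 0.9 as in
# band-limited scalp EEG), plus a small channel-specific residual
noiseMatrix <- function(nCh, n, cfg, graph = NULL) {
  ar1 <- function(m) {
    if (identical(cfg$noise_model, "ar1") && cfg$ar_coef > 0) {
      phi <- cfg$ar_coef
      Xt <- matrix(rnorm(m * n, sd = sqrt(1 - phi^2)), n, m)
      Xf <- stats::filter(Xt, phi, method = "recursive")
      t(matrix(as.numeric(Xf), n, m))   # strip the ts attributes
    } else {
      matrix(rnorm(m * n), m, n)
    }
  }
  if (is.null(graph) || cfg$spatial_mix <= 0) return(ar1(nCh) * cfg$noise_sd_uv)
  # low-rank smooth field (volume conduction of a limited set of sources)
  # plus channel-specific white sensor noise
  r <- min(nCh, cfg$noise_rank %||% 16)
  B <- smoothingOperator(graph, cfg$spatial_passes %||% 5) %*%
    matrix(rnorm(nCh * r), nCh, r)
  Xs <- B %*% ar1(r)
  Xs <- Xs / sd(as.numeric(Xs))
  X <- sqrt(cfg$spatial_mix) * Xs +
    sqrt(1 - cfg$spatial_mix) * matrix(rnorm(nCh * n), nCh, n)
  X * cfg$noise_sd_uv
}

# repeated neighbour-averaging operator (volume-conduction-like smoothing)
smoothingOperator <- function(graph, passes) {
  nCh <- length(graph@adjacency)
  M <- diag(nCh)
  for (i in seq_len(nCh)) {
    nb <- graph@adjacency[[i]]
    M[i, c(i, nb)] <- 1 / (1 + length(nb))
    M[i, setdiff(seq_len(nCh), c(i, nb))] <- 0
  }
  Reduce(`%*%`, rep(list(M), max(1, passes)))
}

#' Simulate one subject of the synthetic cohort
#'
#' EEG = spatiotemporally correlated background noise + cardiac field artifact
#' (QRS template train mixed across channels) + stimulus-locked deviant
#' increments + heartbeat-locked condition-dependent increments on the beats
#' that follow each trial's 5th sound, plus group-dependent trial-to-trial
#' heartbeat-locked variability. Group semantics: MCS-like and CONTROL
#' subjects carry full local and global effects; UWS-like subjects carry
#' attenuated local effects and null global effects; MCS-like subjects get
#' \code{her_trial_variance_ratio} times larger heartbeat-locked response
#' variability.
#'
#' @param config a [simConfig()] list.
#' @param group "MCS", "UWS" or "CONTROL".
#' @param seed RNG seed for this subject.
#' @param subjectId identifier.
#' @return list with \code{recording} ([Recording-class]) and \code{truth}
#'   (ground-truth sidecar: true R-peaks, cardiac mixing, planted windows,
#'   the clean ECG trace, group).
#' @export
simulateSubject <- function(config, group, seed = config$seed, subjectId = "sim01") {
  if (!group %in% c("MCS", "UWS", "CONTROL"))
    stop("simulateSubject: group must be MCS, UWS or CONTROL")
  cfg <- config
  fs <- cfg$fs
  nBxx <- if (group == "CONTROL") cfg$control_blocks_xx else cfg$n_blocks_xx
  nBxy <- if (group == "CONTROL") cfg$control_blocks_xy else cfg$n_blocks_xy
  timing <- cfg[c("fs", "tone_duration_ms", "soa_ms", "iti_range_ms")]

  blocks <- c(rep("XX", nBxx), rep("XY", nBxy))
  ev <- NULL
  t0 <- round(cfg$lead_in_s * fs)
  trialOff <- 0
  for (b in seq_along(blocks)) {
    es <- generateEventStream(blocks[b], cfg$trials_per_block, cfg$rare_fraction,
                              timing, seed = deriveSeed(seed, "events", b),
                              startSample = t0, trialIdOffset = trialOff)
    ev <- rbind(ev, es$events)
    trialOff <- max(es$events$trial_id)
    t0 <- es$endSample + round(cfg$block_gap_s * fs)
  }
  n <- max(ev$onset_sample) + round((1 + cfg$tail_s) * fs)
  durS <- n / fs

  card <- simulateCardiac(durS, fs, cfg$rr_mean_ms, cfg$rr_sd_ms,
                          seed = deriveSeed(seed, "cardiac"), rrFloorMs = cfg$rr_floor_ms)
  layout <- simLayout(cfg)
  graph <- buildNeighborGraph(layout, 4)

  msToIdx <- function(winMs) {
    i0 <- floor(winMs[1] * fs / 1000)
    i1 <- ceiling(winMs[2] * fs / 1000)
    seq(i0, max(i0, i1 - 1))   # half-open in samples
  }
  effCh <- simEffectChannels(layout, graph, cfg$n_effect_channels)

  erpLocalF <- if (group == "UWS") cfg$uws_erp_local_factor else 1
  herLocalF <- if (group == "UWS") cfg$uws_her_local_factor else 1
  globalF <- if (group == "UWS") cfg$uws_global_factor else 1
  varRatio <- if (group == "MCS") cfg$her_trial_variance_ratio else 1

  withSeed(deriveSeed(seed, "eeg"), {
    eeg <- noiseMatrix(cfg$n_channels, n, cfg, graph)
    # smooth dipolar-like cardiac field topography
    mixing <- as.numeric(smoothingOperator(graph, 3) %*% rnorm(cfg$n_channels))
    mixing <- mixing / max(abs(mixing))
    eeg <- eeg + cfg$artifact_gain * outer(mixing, card$ecg)

    fifth <- ev[ev$sound_index == 5, ]
    addBump <- function(lockSample, chans, amp, winIdx) {
      idx <- lockSample + winIdx + 1L     # 0-based lock -> 1-based columns
      keep <- idx >= 1 & idx <= n
      if (!any(keep)) return(invisible(NULL))
      bump <- amp * windowBump(length(winIdx))[keep]
      eeg[chans, idx[keep]] <<- eeg[chans, idx[keep]] +
        matrix(bump, length(chans), sum(keep), byrow = TRUE)
      invisible(NULL)
    }
    erpLocIdx <- msToIdx(cfg$erp_local_window_ms)
    erpGloIdx <- msToIdx(cfg$erp_global_window_ms)
    herLocIdx <- msToIdx(cfg$her_local_window_ms)
    herGloIdx <- msToIdx(cfg$her_global_window_ms)
    herSpanIdx <- seq(0, round(0.5 * fs) - 1)

    # first R-peak strictly after each 5th-sound onset (NA when none)
    lockOf <- function(onset) {
      j <- findInterval(onset, card$rpeaks) + 1L
      if (j <= length(card$rpeaks)) card$rpeaks[j] else NA_real_
    }
    for (k in seq_len(nrow(fifth))) {
      cond <- fifth$condition[k]
      on5 <- fifth$onset_sample[k]
      if (cond %in% c("LDGS", "LDGD") && erpLocalF * cfg$erp_local_amp != 0)
        addBump(on5, effCh, erpLocalF * cfg$erp_local_amp, erpLocIdx)
      if (cond %in% c("LSGD", "LDGD") && globalF * cfg$erp_global_amp != 0)
        addBump(on5, effCh, globalF * cfg$erp_global_amp, erpGloIdx)
      lk <- lockOf(on5)
      if (!is.na(lk)) {
        if (cond %in% c("LDGS", "LDGD") && herLocalF * cfg$her_local_amp != 0)
          addBump(lk, effCh, herLocalF * cfg$her_local_amp, herLocIdx)
        if (cond %in% c("LSGD", "LDGD") && globalF * cfg$her_global_amp != 0)
          addBump(lk, effCh, globalF * cfg$her_global_amp, herGloIdx)
      }
    }
    if (cfg$her_variability_sd > 0) {
      amps <- rnorm(length(card$rpeaks), 0, cfg$her_variability_sd * varRatio)
      for (k in seq_along(card$rpeaks))
        addBump(card$rpeaks[k], effCh, amps[k], herSpanIdx)
    }

    rec <- Recording(eeg, fs, layout, ev, subjectId = subjectId, group = group,
                     preprocLog = "simulated")
    truth <- list(
      true_rpeak_samples = card$rpeaks,
      cardiac_mixing = mixing,
      ecg = card$ecg,
      group = group,
      effect_channels = layout@names[effCh],
      planted_effect_windows = list(
        ERP_LOCAL = list(window_ms = cfg$erp_local_window_ms, amp = erpLocalF * cfg$erp_local_amp),
        ERP_GLOBAL = list(window_ms = cfg$erp_global_window_ms, amp = globalF * cfg$erp_global_amp),
        HER_LOCAL = list(window_ms = cfg$her_local_window_ms, amp = herLocalF * cfg$her_local_amp),
        HER_GLOBAL = list(window_ms = cfg$her_global_window_ms, amp = globalF * cfg$her_global_amp)
      )
    )
    list(recording = rec, truth = truth)
  })
}

#' Simulate a cohort, optionally writing it to disk
#'
#' Per-subject seeds are derived deterministically from the master seed. With
#' \code{outDir} set, each subject is written as EDF + events TSV + layout TSV
#' + ground-truth JSON sidecar and a manifest JSON indexes them; otherwise the
#' subjects are returned in memory.
#'
#' @param config a [simConfig()] list.
#' @param outDir optional output directory.
#' @return list with \code{manifest} (data.frame subject_id, group, seed and,
#'   when written, file paths) and, in-memory mode, \code{subjects} (list of
#'   simulateSubject results).
#' @export
simulateCohort <- function(config, outDir = NULL) {
  counts <- c(MCS = config$n_mcs, UWS = config$n_uws, CONTROL = config$n_control)
  if (sum(counts) == 0) stop("simulateCohort: zero total subjects")
  groups <- rep(names(counts), counts)
  ids <- sprintf("%s%02d", tolower(groups), unlist(lapply(counts, seq_len)))
  seeds <- vapply(ids, function(id) deriveSeed(config$seed, "subject", id), 0L)
  manifest <- data.frame(subject_id = ids, group = groups, seed = seeds,
                         stringsAsFactors = FALSE)
  if (is.null(outDir)) {
    subjects <- lapply(seq_along(ids), function(i)
      simulateSubject(config, groups[i], seed = seeds[i], subjectId = ids[i]))
    names(subjects) <- ids
    return(list(manifest = manifest, subjects = subjects))
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- lapply(seq_along(ids), function(i) {
    s <- simulateSubject(config, groups[i], seed = seeds[i], subjectId = ids[i])
    base <- file.path(outDir, ids[i])
    saveRecording(s$recording, paste0(base, ".edf"), paste0(base, "_events.tsv"),
                  paste0(base, "_layout.tsv"))
    jsonlite::write_json(s$truth, paste0(base, "_truth.json"), auto_unbox = TRUE,
                         digits = NA)
    logMsg("simulate", "wrote ", ids[i])
    c(eeg = paste0(base, ".edf"), events = paste0(base, "_events.tsv"),
      layout = paste0(base, "_layout.tsv"), truth = paste0(base, "_truth.json"))
  })
  manifest$eeg <- vapply(paths, `[[`, "", "eeg")
  manifest$events <- vapply(paths, `[[`, "", "events")
  manifest$layout <- vapply(paths, `[[`, "", "layout")
  manifest$truth <- vapply(paths, `[[`, "", "truth")
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  list(manifest = manifest)
}

#' Simulate subject-level effect maps directly (map-level generator)
#'
#' Generates channels x time contrast maps with EEG-like spatial and temporal
#' correlation (moving-average smoothing in time, neighbour mixing in space)
#' for two groups, optionally planting a group-A effect. Used for fast
#' calibration studies of the cluster-permutation machinery at the map level,
#' bypassing the raw-EEG stages.
#'
#' @param nA,nB group sizes.
#' @param layout a [SensorLayout-class].
#' @param nTime number of time samples per map.
#' @param seed RNG seed.
#' @param noiseSd per-point map noise SD after smoothing (microvolts).
#' @param temporalSpan moving-average span in samples.
#' @param spatialMix neighbour mixing weight in [0, 1).
#' @param effect optional list(channels, time, amp) planted into group A.
#' @return list with \code{A} and \code{B}: lists of channels x time matrices.
#' @export
simulateEffectMaps <- function(nA, nB, layout, nTime, seed = 1, noiseSd = 1,
                               temporalSpan = 5, smoothPasses = 3,
                               smoothShare = 0.9, effect = NULL) {
  graph <- buildNeighborGraph(layout, 4)
  nCh <- length(layout@names)
  # plain neighbour-averaging operator, applied smoothPasses times: emulates
  # the high inter-channel correlation of volume-conducted scalp maps
  M <- diag(nCh)
  for (i in seq_len(nCh)) {
    nb <- graph@adjacency[[i]]
    M[i, c(i, nb)] <- 1 / (1 + length(nb))
    M[i, setdiff(seq_len(nCh), c(i, nb))] <- 0
  }
  Mk <- Reduce(`%*%`, rep(list(M), smoothPasses))
  one <- function() {
    X <- matrix(rnorm(nCh * (nTime + temporalSpan)), nCh, nTime + temporalSpan)
    if (temporalSpan > 1) {
      X <- t(apply(X, 1, function(x)
        as.numeric(stats::filter(x, rep(1 / sqrt(temporalSpan), temporalSpan), sides = 1))))
    }
    X <- X[, (temporalSpan + 1):(temporalSpan + nTime), drop = FALSE]
    Xs <- Mk %*% X
    Xs <- Xs / sd(as.numeric(Xs))
    E <- matrix(rnorm(nCh * nTime), nCh, nTime)
    (sqrt(smoothShare) * Xs + sqrt(1 - smoothShare) * E) * noiseSd
  }
  withSeed(seed, {
    mapsA <- lapply(seq_len(nA), function(i) {
      m <- one()
      if (!is.null(effect)) m[effect$channels, effect$time] <- m[effect$channels, effect$time] + effect$amp
      m
    })
    mapsB <- lapply(seq_len(nB), function(i) one())
    list(A = mapsA, B = mapsB)
  })
}

#' Simulate a combined-effect feature table
#'
#' Draws the four combined clustered effects (ERP global/local, HER
#' global/local) for an MCS-like and a UWS-like group from Gaussian feature
#' distributions following the qualitative group pattern (all effects present
#' in MCS, attenuated local and null global effects in UWS).
#'
#' @param nMcs,nUws group sizes.
#' @param seed RNG seed.
#' @param mcsMean,uwsMean length-4 mean vectors (ERP_global, ERP_local,
#'   HER_global, HER_local), in feature units.
#' @param sd common feature SD.
#' @return data.frame with subject_id, label and the four feature columns.
#' @export
simulateFeatureTable <- function(nMcs = 46, nUws = 40, seed = 1,
                                 mcsMean = c(1.2, 1.6, 0.8, 1.2),
                                 uwsMean = c(0.0, 0.6, 0.1, 0.3),
                                 sd = 1) {
  feats <- c("ERP_global", "ERP_local", "HER_global", "HER_local")
  withSeed(seed, {
    X <- rbind(
      matrix(rnorm(nMcs * 4, rep(mcsMean, each = nMcs), sd), nMcs, 4),
      matrix(rnorm(nUws * 4, rep(uwsMean, each = nUws), sd), nUws, 4)
    )
    colnames(X) <- feats
    data.frame(subject_id = sprintf("s%03d", seq_len(nMcs + nUws)),
               label = rep(c("MCS", "UWS"), c(nMcs, nUws)), X,
               stringsAsFactors = FALSE)
  })
}
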