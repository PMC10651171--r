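#' @include AllClasses.R utils.R io.R simulate.R preprocess.R cardiac.R epochs.R cluster.R surrogate.R stats.R classify.R
NULL

stageTry <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage:%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Analyse one subject: preprocessing, heartbeats, epochs, contrast maps
#'
#' Applies the configured preprocessing chain (band-pass, iterative channel
#' rejection, ICA-ECG recovery, low-correlation interpolation, common-average
#' re-reference), detects and flags heartbeats, builds the stimulus-locked
#' and heartbeat-locked epoch sets, and returns the four contrast maps plus
#' the whole-protocol HER summary.
#'
#' @param recording a [Recording-class].
#' @param config nested configuration (see [defaultConfig()]), plus an
#'   optional \code{pipeline} block with logical switches \code{bandpass},
#'   \code{reject_channels}, \code{ica}, \code{interpolate},
#'   \code{rereference}, a channel \code{subset}, and \code{ecg_source}
#'   ("ica" or "external").
#' @param ecg optional external ECG trace (required when
#'   \code{ecg_source = "external"}).
#' @return list with recording, hb, epochs, maps (ERP/HER x LOCAL/GLOBAL),
#'   herSummary, latencies, reports.
#' @export
analyzeSubject <- function(recording, config = defaultConfig(), ecg = NULL) {
  pl <- mergeConfig(list(bandpass = TRUE, reject_channels = TRUE, ica = TRUE,
                         interpolate = TRUE, rereference = TRUE, subset = NULL,
                         ecg_source = "ica"),
                    if (is.null(config$pipeline)) list() else config$pipeline)
  reports <- list()
  rec <- recording
  if (isTRUE(pl$bandpass))
    rec <- stageTry("bandpass", bandpassFilter(rec, config$filter$low_hz,
                                               config$filter$high_hz,
                                               config$filter$order, config$filter$mode))
  if (isTRUE(pl$reject_channels)) {
    rr <- stageTry("reject", rejectChannelsZscore(rec, config$reject$z_threshold,
                                                  config$reject$max_iter))
    rec <- rr$recording; reports$reject <- rr$report
  }
  if (identical(pl$ecg_source, "ica") && isTRUE(pl$ica)) {
    ic <- stageTry("ica", extractIcaEcg(rec, seed = deriveSeed(config$seed %||% 1, "ica"),
                                        minKurtosis = config$ica$min_kurtosis,
                                        maxIter = config$ica$max_iter, tol = config$ica$tol))
    rec <- ic$recording; ecg <- ic$ecg; reports$ica <- ic$report
  } else if (is.null(ecg)) {
    stop("[stage:ica] no ICA requested and no external ECG provided")
  }
  graph <- buildNeighborGraph(rec@layout, config$neighbor$max_distance_cm)
  if (isTRUE(pl$interpolate)) {
    ir <- stageTry("interpolate",
                   interpolateLowCorrelationChannels(rec, graph, config$interp$corr_threshold,
                                                     config$interp$weighting))
    rec <- ir$recording; reports$interp <- ir$report
  }
  if (isTRUE(pl$rereference))
    rec <- stageTry("rereference", rereferenceAndSubset(rec, pl$subset))
  hb <- stageTry("heartbeats", {
    h <- detectRPeaks(ecg, rec@fs, config$rpeak$window_ms, config$rpeak$refractory_ms,
                      config$rpeak$floor_frac)
    if (length(h@ibiMs) >= 3) h <- flagEctopic(h, config$ectopic$deriv_threshold)
    h
  })
  ec <- config$epochs
  erp <- stageTry("epochs_erp", epochStimulus(rec, ec$amp_reject_uv, ec$erp_length_ms))
  her <- stageTry("epochs_her",
                  epochHeartbeatPostStimulus(rec, hb, ec$amp_reject_uv, ec$ibi_floor_ms,
                                             ec$stim_guard_ms, ec$her_length_ms,
                                             ec$guard_all_sounds))
  herAll <- stageTry("epochs_her_all",
                     epochAllHeartbeats(rec, hb, ec$amp_reject_uv, ec$ibi_floor_ms,
                                        ec$her_length_ms))
  sid <- rec@subjectId
  maps <- list(
    ERP_LOCAL = subjectEffect(erp, "LOCAL", subjectId = sid, pooling = ec$pooling),
    ERP_GLOBAL = subjectEffect(erp, "GLOBAL", subjectId = sid, pooling = ec$pooling),
    HER_LOCAL = subjectEffect(her, "LOCAL", subjectId = sid, pooling = ec$pooling),
    HER_GLOBAL = subjectEffect(her, "GLOBAL", subjectId = sid, pooling = ec$pooling)
  )
  list(recording = rec, hb = hb,
       epochs = list(erp = erp, her = her, herAll = herAll), maps = maps,
       herSummary = herSummaryWholeProtocol(herAll),
       latencies = subjectMeanLatencies(rec, hb), reports = reports)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full cohort pipeline on a simulated or loaded cohort
#'
#' Orchestrates simulate (optional) -> per-subject analysis -> group
#' cluster-permutation tests (ERP/HER x local/global and whole-protocol HER
#' variance) -> per-subject combined clustered effects -> within-group median
#' tests and between-effect Spearman correlations with Bonferroni control ->
#' optional surrogate-heartbeat control -> cross-validated classification.
#' Any stage failure halts with a stage-tagged error.
#'
#' @param config nested list: \code{sim} ([simConfig()] overrides), the
#'   [defaultConfig()] analysis blocks, a \code{pipeline} block (see
#'   [analyzeSubject()]; plus \code{surrogates} logical and
#'   \code{n_partitions}), and \code{seed}.
#' @param outDir optional directory for the JSON index and TSV outputs.
#' @return list (report bundle): subjects, clusterResults, combined effects,
#'   table1, table2, latencyBalance, classification, surrogates (optional).
#' @export
runPipeline <- function(config = list(), outDir = NULL) {
  cfg <- mergeConfig(defaultConfig(), config)
  cfg$seed <- cfg$seed %||% 1L
  simCfg <- do.call(simConfig, c(cfg$sim %||% list(), list(seed = cfg$seed)))
  pl <- mergeConfig(list(surrogates = FALSE, n_partitions = cfg$cluster$n_partitions,
                         ecg_source = "ica"), cfg$pipeline %||% list())
  cfg$pipeline <- pl

  cohort <- stageTry("simulate", simulateCohort(simCfg))
  subjects <- cohort$subjects
  groups <- cohort$manifest$group
  if (sum(groups == "MCS") < 2 || sum(groups == "UWS") < 2)
    stop("[stage:cluster] need at least 2 MCS and 2 UWS subjects")

  analyses <- lapply(seq_along(subjects), function(i) {
    ecg <- if (identical(pl$ecg_source, "external")) subjects[[i]]$truth$ecg else NULL
    a <- analyzeSubject(subjects[[i]]$recording, cfg, ecg = ecg)
    logMsg("pipeline", "subject ", cohort$manifest$subject_id[i], " analysed")
    a
  })

  # group analysis on the channels every subject retains
  common <- Reduce(intersect, lapply(analyses, function(a) a$recording@layout@names))
  lay0 <- subjects[[1]]$recording@layout
  idx <- match(common, lay0@names)
  layout <- SensorLayout(common, lay0@positions[idx, , drop = FALSE])
  graph <- buildNeighborGraph(layout, cfg$neighbor$max_distance_cm)
  subsetMap <- function(m) m@map[match(common, m@channelNames), , drop = FALSE]

  iA <- which(groups == "MCS"); iB <- which(groups == "UWS")
  effectKeys <- c("ERP_LOCAL", "ERP_GLOBAL", "HER_LOCAL", "HER_GLOBAL")
  clusterResults <- list()
  combined <- list()
  for (key in effectKeys) {
    mapsAll <- lapply(analyses, function(a) subsetMap(a$maps[[key]]))
    clusterResults[[key]] <- stageTry(paste0("cluster_", key),
      permutationTest(mapsAll[iA], mapsAll[iB], graph, nPartitions = pl$n_partitions,
                      seed = deriveSeed(cfg$seed, "perm", key),
                      alpha = cfg$cluster$alpha, minChannels = cfg$cluster$min_channels,
                      fs = simCfg$fs))
    combined[[key]] <- combinedSignificantEffect(mapsAll, clusterResults[[key]],
                                                 alpha = cfg$cluster$alpha)
  }
  varMaps <- lapply(analyses, function(a) {
    m <- a$herSummary$variance
    m[match(common, a$recording@layout@names), , drop = FALSE]
  })
  clusterResults$HER_VARIANCE <- stageTry("cluster_variance",
    permutationTest(varMaps[iA], varMaps[iB], graph, nPartitions = pl$n_partitions,
                    seed = deriveSeed(cfg$seed, "perm", "var"), fs = simCfg$fs))

  # Table-1-style within-group median tests (2 groups x 2 signals x 2 levels)
  table1 <- do.call(rbind, lapply(effectKeys, function(key) {
    do.call(rbind, lapply(list(c("MCS", "iA"), c("UWS", "iB")), function(g) {
      vals <- combined[[key]][if (g[1] == "MCS") iA else iB]
      if (all(is.na(vals))) {
        data.frame(group = g[1], effect = key, Z = NA, p = NA, n = sum(!is.na(vals)))
      } else {
        r <- medianVsZeroTest(vals[!is.na(vals)], mode = cfg$stats$median_test)
        data.frame(group = g[1], effect = key, Z = r$Z, p = r$p, n = r$n)
      }
    }))
  }))
  table1 <- bonferroniAdjust(table1, m = cfg$stats$bonferroni_m)

  # Table-2-style Spearman correlations between effects, per group
  pairings <- list(c("ERP_GLOBAL", "ERP_LOCAL"), c("HER_GLOBAL", "ERP_GLOBAL"),
                   c("HER_GLOBAL", "HER_LOCAL"), c("HER_LOCAL", "ERP_LOCAL"))
  table2 <- do.call(rbind, lapply(pairings, function(pr) {
    do.call(rbind, lapply(c("MCS", "UWS"), function(g) {
      ii <- if (g == "MCS") iA else iB
      x <- combined[[pr[1]]][ii]; y <- combined[[pr[2]]][ii]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 5) {
        data.frame(group = g, pair = paste(pr, collapse = "_vs_"), R = NA, p = NA, n = sum(ok))
      } else {
        r <- spearmanAssoc(x[ok], y[ok])
        data.frame(group = g, pair = paste(pr, collapse = "_vs_"), R = r$R, p = r$p, n = r$n)
      }
    }))
  }))
  table2 <- bonferroniAdjust(table2, m = cfg$stats$bonferroni_m)

  latency <- do.call(rbind, lapply(analyses[c(iA, iB)], `[[`, "latencies"))
  latencyBalance <- latencyBalanceTest(latency)

  feat <- data.frame(subject_id = cohort$manifest$subject_id[c(iA, iB)],
                     label = groups[c(iA, iB)],
                     ERP_global = combined$ERP_GLOBAL[c(iA, iB)],
                     ERP_local = combined$ERP_LOCAL[c(iA, iB)],
                     HER_global = combined$HER_GLOBAL[c(iA, iB)],
                     HER_local = combined$HER_LOCAL[c(iA, iB)],
                     stringsAsFactors = FALSE)
  classification <- NULL
  if (all(is.finite(as.matrix(feat[, 3:6])))) {
    classification <- stageTry("classify",
      runAllSubsets(feat, seed = deriveSeed(cfg$seed, "cv"), k = cfg$classify$k))
  }

  surr <- NULL
  if (isTRUE(pl$surrogates)) {
    subj <- lapply(seq_along(analyses), function(i)
      list(recording = analyses[[i]]$recording, hb = analyses[[i]]$hb))
    surr <- lapply(c(LOCAL = "LOCAL", GLOBAL = "GLOBAL"), function(lv)
      stageTry(paste0("surrogates_", lv),
               surrogateAnalysis(subj, groups, lv, graph,
                                 nSurrogates = cfg$surrogate$n_surrogates,
                                 nPartitions = cfg$surrogate$n_partitions,
                                 seed = deriveSeed(cfg$seed, "surr", lv))))
  }

  bundle <- list(manifest = cohort$manifest, clusterResults = clusterResults,
                 combined = combined, table1 = table1, table2 = table2,
                 latencyBalance = latencyBalance, features = feat,
                 classification = classification, surrogates = surr,
                 seed = cfg$seed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    saveTable(table1, file.path(outDir, "table1.tsv"))
    saveTable(table2, file.path(outDir, "table2.tsv"))
    saveTable(latencyBalance, file.path(outDir, "latency_balance.tsv"))
    saveTable(feat, file.path(outDir, "combined_effects.tsv"))
    index <- list(
      seed = cfg$seed,
      n_subjects = nrow(cohort$manifest),
      clusters = lapply(clusterResults, function(cr)
        lapply(cr@clusters, function(cl)
          cl[c("sign", "nChannels", "size", "stat", "latencyMs", "mcP")])),
      classification = if (!is.null(classification))
        lapply(classification, function(r)
          list(features = r$feature_subset, accuracy = r$accuracy)),
      surrogate_p = if (!is.null(surr)) lapply(surr, `[[`, "p"),
      outputs = c("table1.tsv", "table2.tsv", "latency_balance.tsv",
                  "combined_effects.tsv")
    )
    jsonlite::write_json(index, file.path(outDir, "index.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  bundle
}
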