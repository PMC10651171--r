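#' @include AllClasses.R
NULL

#' Accessors for herclust objects
#'
#' Small generic accessor family: \code{eegData} returns the channels x samples
#' matrix, \code{samplingRate} the rate in Hz, \code{sensorLayout} the montage,
#' \code{auditoryEvents} the event table, \code{channelNames} the labels,
#' \code{rpeaks} the R-peak samples (0-based), \code{ibi} the interbeat
#' intervals in ms, \code{ectopicFlags} the per-interval flags,
#' \code{epochData} the epochs x channels x time array, \code{epochConditions}
#' the per-epoch labels, \code{rejectionLog} the epoch disposition table,
#' \code{effectMatrix} the channels x time contrast map, and \code{clusters}
#' the cluster list of a test result.
#'
#' @param x a herclust object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setMethod("eegData", "Recording", function(x) x@eeg)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "HeartbeatSeries", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)

#' @rdname accessors
#' @export
setGeneric("sensorLayout", function(x) standardGeneric("sensorLayout"))
#' @rdname accessors
#' @export
setMethod("sensorLayout", "Recording", function(x) x@layout)

#' @rdname accessors
#' @export
setGeneric("auditoryEvents", function(x) standardGeneric("auditoryEvents"))
#' @rdname accessors
#' @export
setMethod("auditoryEvents", "Recording", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "Recording", function(x) x@layout@names)
#' @rdname accessors
#' @export
setMethod("channelNames", "SensorLayout", function(x) x@names)
#' @rdname accessors
#' @export
setMethod("channelNames", "NeighborGraph", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "EffectMap", function(x) x@channelNames)

#' @rdname accessors
#' @export
setGeneric("sensorPositions", function(x) standardGeneric("sensorPositions"))
#' @rdname accessors
#' @export
setMethod("sensorPositions", "SensorLayout", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "NeighborGraph", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("rpeaks", function(x) standardGeneric("rpeaks"))
#' @rdname accessors
#' @export
setMethod("rpeaks", "HeartbeatSeries", function(x) x@rpeakSamples)

#' @rdname accessors
#' @export
setGeneric("ibi", function(x) standardGeneric("ibi"))
#' @rdname accessors
#' @export
setMethod("ibi", "HeartbeatSeries", function(x) x@ibiMs)

#' @rdname accessors
#' @export
setGeneric("ectopicFlags", function(x) standardGeneric("ectopicFlags"))
#' @rdname accessors
#' @export
setMethod("ectopicFlags", "HeartbeatSeries", function(x) x@ectopicFlags)

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("epochConditions", function(x) standardGeneric("epochConditions"))
#' @rdname accessors
#' @export
setMethod("epochConditions", "EpochSet", function(x) x@conditions)

#' @rdname accessors
#' @export
setGeneric("rejectionLog", function(x) standardGeneric("rejectionLog"))
#' @rdname accessors
#' @export
setMethod("rejectionLog", "EpochSet", function(x) x@rejectionLog)

#' @rdname accessors
#' @export
setGeneric("effectMatrix", function(x) standardGeneric("effectMatrix"))
#' @rdname accessors
#' @export
setMethod("effectMatrix", "EffectMap", function(x) x@map)

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setMethod("clusters", "ClusterResult", function(x) x@clusters)

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))
#' @rdname accessors
#' @export
setMethod("zMatrix", "ClusterResult", function(x) x@z)

#' @rdname accessors
#' @export
setGeneric("permDistribution", function(x) standardGeneric("permDistribution"))
#' @rdname accessors
#' @export
setMethod("permDistribution", "ClusterResult", function(x) x@permDistribution)

#' @rdname accessors
#' @export
setGeneric("combinedEffects", function(x) standardGeneric("combinedEffects"))
#' @rdname accessors
#' @export
setMethod("combinedEffects", "ClusterResult", function(x) x@combinedEffects)

setMethod("show", "SensorLayout", function(object) {
  cat("SensorLayout with", length(object@names), "channels\n")
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording '%s' (%s): %d channels x %d samples @ %g Hz, %d events\n",
              object@subjectId, object@group, nrow(object@eeg), ncol(object@eeg),
              object@fs, nrow(object@events)))
  if (length(object@preprocLog))
    cat("  preprocessing:", paste(object@preprocLog, collapse = " -> "), "\n")
})

setMethod("show", "NeighborGraph", function(object) {
  deg <- lengths(object@adjacency)
  cat(sprintf("NeighborGraph: %d channels, max distance %g cm, mean degree %.2f\n",
              length(object@adjacency), object@maxDistanceCm, mean(deg)))
})

setMethod("show", "HeartbeatSeries", function(object) {
  cat(sprintf("HeartbeatSeries (%s): %d R-peaks", object@source, length(object@rpeakSamples)))
  if (length(object@ibiMs))
    cat(sprintf(", median IBI %.0f ms, %d ectopic-flagged", stats::median(object@ibiMs),
                sum(object@ectopicFlags)))
  cat("\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet (%s): %d epochs x %d channels x %d samples (%g ms @ %g Hz)\n",
              object@lock, d[1], d[2], d[3], object@epochLengthMs, object@fs))
  rl <- object@rejectionLog
  if (nrow(rl) && any(!rl$accepted)) {
    tab <- table(rl$reason[!rl$accepted])
    cat("  rejected:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "EffectMap", function(object) {
  cat(sprintf("EffectMap %s %s '%s': %d channels x %d samples, n(dev)=%d n(std)=%d\n",
              object@signal, object@level, object@subjectId, nrow(object@map),
              ncol(object@map), object@nDeviant, object@nStandard))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d clusters, %d partitions%s\n", length(object@clusters),
              object@nPartitions, if (object@exhaustive) " (exhaustive)" else ""))
  for (cl in object@clusters) {
    cat(sprintf("  %s cluster: %d channels, size %d, stat %.3f, latency %.0f-%.0f ms, mc p %s\n",
                cl$sign, cl$nChannels, cl$size, cl$stat, cl$latencyMs[1], cl$latencyMs[2],
                format(cl$mcP)))
  }
})
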