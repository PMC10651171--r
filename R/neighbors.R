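#' @include AllClasses.R
NULL

#' Build the channel neighbourhood graph
#'
#' Two sensors are neighbours when their Euclidean distance is at most
#' \code{maxDistanceCm} (inclusive boundary). Isolated channels are allowed.
#'
#' @param layout a [SensorLayout-class].
#' @param maxDistanceCm neighbourhood radius in cm (default 4).
#' @return A [NeighborGraph-class].
#' @export
buildNeighborGraph <- function(layout, maxDistanceCm = 4) {
  pos <- layout@positions
  if (nrow(pos) < 1 || !all(is.finite(pos)))
    stop("buildNeighborGraph: need at least one channel with finite positions")
  d <- as.matrix(dist(pos))
  adj <- lapply(seq_len(nrow(pos)), function(i) {
    which(d[i, ] <= maxDistanceCm & seq_len(nrow(pos)) != i)
  })
  new("NeighborGraph", adjacency = adj, maxDistanceCm = maxDistanceCm,
      channelNames = layout@names)
}

#' Pairwise channel distances of a layout (cm)
#' @param layout a [SensorLayout-class].
#' @return symmetric distance matrix.
#' @export
channelDistances <- function(layout) {
  d <- as.matrix(dist(layout@positions))
  dimnames(d) <- list(layout@names, layout@names)
  d
}
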