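#' @include accessors.R regions.R
NULL

#' Threshold a directed connectivity matrix into an edge set
#'
#' Retains ordered edges whose value strictly exceeds the threshold and
#' reports their count and summed intensity. `NA` entries (failed pairs)
#' are never retained.
#'
#' @param conn a directed [ConnMatrix-class].
#' @param threshold retention threshold on the metric value.
#' @return list with `edges` (data.frame `from`, `to`, `weight`),
#'   `nEdges`, `totalIntensity`, `threshold`, and `nodes`.
#' @examples
#' # see grangerPairwise(); threshold its $gc element
#' @export
thresholdDirected <- function(conn, threshold) {
  if (!conn@directed) stop("parameter error: matrix is not directed")
  v <- conn@values
  if (threshold < 0 && conn@metric %in% c("granger", "pte", "granger_binary"))
    warning("negative threshold for the non-negative metric '", conn@metric,
            "'; all present edges will be retained")
  sel <- which(!is.na(v) & v > threshold & row(v) != col(v), arr.ind = TRUE)
  labels <- rownames(v)
  edges <- data.frame(from = labels[sel[, 1]], to = labels[sel[, 2]],
                      weight = v[sel])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, nEdges = nrow(edges),
       totalIntensity = sum(edges$weight), threshold = threshold,
       nodes = labels)
}

#' Hemispheric partition of a directed edge set
#'
#' Classifies retained edges by endpoint hemispheres: any edge touching a
#' midline channel is `midline_involved`; otherwise edges within the left
#' or right hemisphere are `intra_left` / `intra_right`, and edges with one
#' endpoint on each side are `cross`.
#'
#' @param edgeSet result of [thresholdDirected()].
#' @param regions a [RegionMap-class] (hemisphere lookup; labels outside
#'   the map fall back to the 10-20 suffix rule).
#' @return data.frame with columns `category`, `count`, `intensity`.
#' @export
interhemisphericSummary <- function(edgeSet, regions = standardRegionMap()) {
  cats <- c("intra_left", "intra_right", "cross", "midline_involved")
  edges <- edgeSet$edges
  out <- data.frame(category = cats, count = 0L, intensity = 0)
  if (nrow(edges)) {
    hf <- hemisphereOf(regions, edges$from)
    ht <- hemisphereOf(regions, edges$to)
    cat <- ifelse(hf == "midline" | ht == "midline", "midline_involved",
           ifelse(hf != ht, "cross",
           ifelse(hf == "left", "intra_left", "intra_right")))
    aggC <- tapply(rep(1L, nrow(edges)), factor(cat, cats), sum, default = 0L)
    aggI <- tapply(edges$weight, factor(cat, cats), sum, default = 0)
    out$count <- as.integer(aggC)
    out$intensity <- as.numeric(aggI)
  }
  out
}
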