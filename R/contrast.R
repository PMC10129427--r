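#' @include accessors.R group-stats.R roc.R
NULL

.connFiniteValues <- function(conn) {
  v <- conn@values
  vals <- if (conn@directed) v[row(v) != col(v)] else v[upper.tri(v)]
  vals[is.finite(vals)]
}

#' Group contrast of connectivity matrices
#'
#' Compares one connectivity metric/band between two cohorts with a
#' Mann-Whitney U test and a ROC curve. In `per_edge_pooled` mode all
#' finite off-diagonal values (upper triangle for undirected metrics) are
#' pooled across subjects within each group -- the mode that yields the
#' very large rank statistics typical of edge-level reporting, at the cost
#' of treating dependent edges as independent observations. In
#' `per_subject_mean` mode each subject is first reduced to the mean of its
#' finite edges, giving one independent value per subject.
#'
#' @param cohortA,cohortB lists of [ConnMatrix-class] objects sharing
#'   metric, band and node set.
#' @param pooling "per_edge_pooled" (default) or "per_subject_mean".
#' @param positive which cohort plays the positive class in the ROC
#'   ("A" or "B", default "B").
#' @return list with `test` (a [GroupTestResult-class], group A first),
#'   `roc` (a [ROCCurve-class]), `metric`, `band`, `pooling`, and the
#'   pooled value counts `nA`, `nB`.
#' @export
contrastConnectivity <- function(cohortA, cohortB,
                                 pooling = c("per_edge_pooled",
                                             "per_subject_mean"),
                                 positive = c("B", "A")) {
  pooling <- match.arg(pooling)
  positive <- match.arg(positive)
  all_ <- c(cohortA, cohortB)
  if (!length(cohortA) || !length(cohortB))
    stop("contract error: both cohorts must be non-empty")
  metric <- all_[[1]]@metric
  band <- all_[[1]]@band
  nodes <- sort(rownames(all_[[1]]@values))
  for (m in all_) {
    if (m@metric != metric || m@band != band)
      stop("contract error: cohorts mix metrics or bands (",
           m@metric, "/", m@band, " vs ", metric, "/", band, ")")
    if (!identical(sort(rownames(m@values)), nodes))
      stop("contract error: cohorts have different node sets")
  }
  pool <- function(cohort) {
    if (pooling == "per_edge_pooled")
      unlist(lapply(cohort, .connFiniteValues))
    else vapply(cohort, function(m) mean(.connFiniteValues(m)), 0)
  }
  va <- pool(cohortA)
  vb <- pool(cohortB)
  test <- mannWhitney(va, vb, mode = "normal", pooling = pooling)
  roc <- rocAuc(c(va, vb), rep(c("A", "B"), c(length(va), length(vb))),
                positive = positive)
  list(test = test, roc = roc, metric = metric, band = band,
       pooling = pooling, nA = length(va), nB = length(vb))
}
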