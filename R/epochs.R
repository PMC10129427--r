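#' @include accessors.R
NULL

#' Split a recording into epochs and reject high-amplitude ones
#'
#' Cuts the recording into consecutive non-overlapping epochs and drops any
#' epoch whose peak absolute amplitude on any channel exceeds the limit.
#' This amplitude criterion is a deterministic stand-in for artifact
#' screening; component-based artifact removal is out of scope and left to
#' external tooling.
#'
#' @param rec an [EEGRecording-class].
#' @param epochLength epoch duration in seconds (default 2).
#' @param amplitudeLimit rejection threshold in microvolts (default 100).
#' @return An [EpochSet-class]; `keptMask(x)` records the decision for every
#'   raw epoch.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 2500), 2), 250, c("C3", "C4"))
#' eps <- epochAndReject(rec, 2, 100)
#' sum(keptMask(eps))
#' @export
epochAndReject <- function(rec, epochLength = 2, amplitudeLimit = 100) {
  fs <- rec@rate
  len <- as.integer(round(epochLength * fs))
  if (len < 2L) stop("parameter error: epoch length must span at least 2 samples")
  if (amplitudeLimit <= 0) stop("parameter error: amplitude limit must be > 0")
  nEpoch <- ncol(rec@samples) %/% len
  if (nEpoch < 1L) stop("parameter error: recording shorter than one epoch")
  keep <- logical(nEpoch)
  eps <- vector("list", nEpoch)
  for (e in seq_len(nEpoch)) {
    m <- rec@samples[, ((e - 1L) * len + 1L):(e * len), drop = FALSE]
    keep[e] <- max(abs(m)) <= amplitudeLimit
    if (keep[e]) eps[[e]] <- m
  }
  if (!any(keep))
    stop("empty-result error: no epochs survived the ", amplitudeLimit,
         " uV amplitude limit")
  new("EpochSet", epochs = eps[keep], rate = fs, labels = rec@labels,
      epochLength = len / fs, keptMask = keep)
}

# Contiguous kept runs (in samples) implied by an epoch rejection mask.
# Adjacent kept epochs are merged so that segment-based estimators (phase
# transfer entropy, Granger causality) can use long artifact-free stretches
# of the continuous recording.
.keptRuns <- function(mask, epochSamples) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  kept <- which(r$values)
  data.frame(start = (starts[kept] - 1L) * epochSamples + 1L,
             length = r$lengths[kept] * epochSamples)
}

# Rebuild an EpochSet view over a (filtered) recording using an existing
# rejection mask, without re-screening amplitudes.
.epochsFromMask <- function(rec, mask, epochSamples) {
  idx <- which(mask)
  eps <- lapply(idx, function(e)
    rec@samples[, ((e - 1L) * epochSamples + 1L):(e * epochSamples), drop = FALSE])
  new("EpochSet", epochs = eps, rate = rec@rate, labels = rec@labels,
      epochLength = epochSamples / rec@rate, keptMask = mask)
}
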