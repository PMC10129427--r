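#' @include AllClasses.R
NULL

#' Construct an EEG recording
#'
#' @param samples numeric matrix, channels x timepoints (microvolts).
#' @param rate sampling rate in Hz.
#' @param labels channel labels; defaults to the matrix rownames.
#' @param meta list of provenance fields.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(500), 2), rate = 250, labels = c("C3", "C4"))
#' nChannels(rec)
#' @export
EEGRecording <- function(samples, rate, labels = rownames(samples), meta = list()) {
  samples <- as.matrix(samples)
  if (is.null(labels)) stop("channel labels are required")
  storage.mode(samples) <- "double"
  rownames(samples) <- labels
  new("EEGRecording", samples = samples, rate = as.numeric(rate),
      labels = as.character(labels), meta = meta)
}

#' @rdname EEGRecording
#' @param object,x an object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname EEGRecording
#' @export
setMethod("samples", "EEGRecording", function(x) x@samples)

#' @rdname EEGRecording
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname EEGRecording
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @rdname EEGRecording
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@rate)

#' @rdname EEGRecording
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname EEGRecording
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@labels)
#' @rdname EEGRecording
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@labels)
#' @rdname EEGRecording
#' @export
setMethod("channelLabels", "ConnMatrix", function(x) rownames(x@values))

#' @rdname EEGRecording
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname EEGRecording
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@samples))
#' @rdname EEGRecording
#' @export
setMethod("nChannels", "EpochSet", function(x) length(x@labels))

#' @rdname EEGRecording
#' @export
setGeneric("recordingMeta", function(x) standardGeneric("recordingMeta"))
#' @rdname EEGRecording
#' @export
setMethod("recordingMeta", "EEGRecording", function(x) x@meta)

#' Epochs and rejection mask of an EpochSet
#' @param x an [EpochSet-class].
#' @return `epochs()`: list of matrices; `keptMask()`: logical vector over
#'   the raw epochs; `epochLength()`: seconds.
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname epochs
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname epochs
#' @export
setGeneric("keptMask", function(x) standardGeneric("keptMask"))
#' @rdname epochs
#' @export
setMethod("keptMask", "EpochSet", function(x) x@keptMask)
#' @rdname epochs
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))
#' @rdname epochs
#' @export
setMethod("epochLength", "EpochSet", function(x) x@epochLength)

#' Connectivity matrix accessors
#' @param x a [ConnMatrix-class].
#' @return `connValues()`: the numeric matrix; `connMetric()`, `connBand()`:
#'   character scalars; `isDirected()`: logical.
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))
#' @rdname connValues
#' @export
setMethod("connValues", "ConnMatrix", function(x) x@values)
#' @rdname connValues
#' @export
setGeneric("connMetric", function(x) standardGeneric("connMetric"))
#' @rdname connValues
#' @export
setMethod("connMetric", "ConnMatrix", function(x) x@metric)
#' @rdname connValues
#' @export
setGeneric("connBand", function(x) standardGeneric("connBand"))
#' @rdname connValues
#' @export
setMethod("connBand", "ConnMatrix", function(x) x@band)
#' @rdname connValues
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))
#' @rdname connValues
#' @export
setMethod("isDirected", "ConnMatrix", function(x) x@directed)

#' Power summary accessors
#' @param x a [PowerSummary-class].
#' @return `dtabr()`: the (delta+theta)/(alpha+beta) ratio; `bandRatio()`,
#'   `regionRatio()`: named shares summing to one; `bandPower()`: the
#'   bands-x-channels absolute power matrix.
#' @export
setGeneric("dtabr", function(x) standardGeneric("dtabr"))
#' @rdname dtabr
#' @export
setMethod("dtabr", "PowerSummary", function(x) x@dtabr)
#' @rdname dtabr
#' @export
setGeneric("bandRatio", function(x) standardGeneric("bandRatio"))
#' @rdname dtabr
#' @export
setMethod("bandRatio", "PowerSummary", function(x) x@bandRatio)
#' @rdname dtabr
#' @export
setGeneric("regionRatio", function(x) standardGeneric("regionRatio"))
#' @rdname dtabr
#' @export
setMethod("regionRatio", "PowerSummary", function(x) x@regionRatio)
#' @rdname dtabr
#' @export
setGeneric("bandPower", function(x) standardGeneric("bandPower"))
#' @rdname dtabr
#' @export
setMethod("bandPower", "PowerSummary", function(x) x@bandPower)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@rate,
              ncol(object@samples) / object@rate))
  cat("  channels:", paste(head(object@labels, 8), collapse = " "),
      if (length(object@labels) > 8) "..." else "", "\n")
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf("EpochSet: %d/%d epochs kept, %g s each, %d channels at %g Hz\n",
              length(object@epochs), length(object@keptMask),
              object@epochLength, length(object@labels), object@rate))
})

setMethod("show", "SpectrumTable", function(object) {
  cat(sprintf("SpectrumTable: %d channels, %d frequencies (%g..%g Hz)\n",
              nrow(object@psd), length(object@freqs), min(object@freqs),
              max(object@freqs)))
})

setMethod("show", "PowerSummary", function(object) {
  cat("PowerSummary\n  band ratios: ",
      paste(sprintf("%s=%.3f", names(object@bandRatio), object@bandRatio),
            collapse = " "), "\n",
      " region ratios:",
      paste(sprintf("%s=%.3f", names(object@regionRatio), object@regionRatio),
            collapse = " "), "\n",
      sprintf(" DTABR: %.3f\n", object@dtabr))
})

setMethod("show", "ConnMatrix", function(object) {
  v <- object@values[row(object@values) != col(object@values)]
  cat(sprintf("ConnMatrix: %s [%s], %s, %d nodes; off-diagonal range %.4g..%.4g (%d NA)\n",
              object@metric, object@band,
              if (object@directed) "directed" else "undirected",
              nrow(object@values), suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
})

setMethod("show", "VARModel", function(object) {
  cat(sprintf("VARModel: order %d (%s), %s\n", object@order,
              paste(object@channels, collapse = " ~ "),
              if (object@stable) "stable" else "UNSTABLE"))
})

setMethod("show", "GroupTestResult", function(object) {
  cat(sprintf("Mann-Whitney U = %g, Z = %.3f, p = %.4g (n1 = %d, n2 = %d, %s)%s\n",
              object@u, object@z, object@p, object@n1, object@n2, object@mode,
              if (object@degenerate) " [degenerate]" else ""))
})

setMethod("show", "ROCCurve", function(object) {
  cat(sprintf("ROC: AUC = %.4f (95%% CI %.4f-%.4f), n+ = %d, n- = %d\n",
              object@auc, object@ciLow, object@ciHigh, object@n1, object@n2))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec '%s': %d channels at %g Hz, %g s, %d directed edges, seed %d\n",
              object@profile, length(object@labels), object@rate,
              object@durationS, nrow(object@couplingGraph), object@seed))
})
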